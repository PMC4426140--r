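# Independent oracle: damped fixed-point iteration of the pre-rearrangement
# recursion for the extinction probabilities (general F), kept deliberately
# separate from the package's quadratic solver.
fp_extinction <- function(sc, damp = 0.5, tol = 1e-13, maxit = 2e5) {
  I <- sc$I; J <- sc$J; Fn <- sc$F
  Q <- array(0, dim = c(I + 1, J + 1, Fn + 1))
  for (it in seq_len(maxit)) {
    Qn <- Q
    for (i in 0:I) for (j in 0:J) for (f in 0:Fn) {
      s <- sigma_of(sc$selection, i, j, f)
      rt <- r_total(sc$recombination, i, j)
      rl <- if (i > 0) vapply(0:(i - 1), function(k)
        r_target(sc$recombination, i, j, "left", k), numeric(1)) else numeric()
      rr <- if (j > 0) vapply(0:(j - 1), function(k)
        r_target(sc$recombination, i, j, "right", k), numeric(1)) else numeric()
      w <- choose(f, 0:f) * 0.5^f
      acc <- 0
      for (g in 0:f) {
        acc <- acc + w[g + 1] * (1 - rt) * Q[i + 1, j + 1, g + 1] * Q[i + 1, j + 1, f + 1]
        if (i > 0) acc <- acc + w[g + 1] * sum(rl * Q[seq_len(i), j + 1, g + 1]) * Q[i + 1, j + 1, f + 1]
        if (j > 0) acc <- acc + w[g + 1] * sum(rr * Q[i + 1, seq_len(j), g + 1]) * Q[i + 1, j + 1, f + 1]
      }
      Qn[i + 1, j + 1, f + 1] <- (1 - s) / (2 - s) + acc / (2 - s)
    }
    if (max(abs(Qn - Q)) < tol) return(damp * Qn + (1 - damp) * Q)
    Q <- damp * Qn + (1 - damp) * Q
  }
  Q
}

# random small scenario for property-style tests
random_scenario <- function(I = sample(0:2, 1), J = sample(0:2, 1),
                            F = sample(0:2, 1), N = 10000) {
  sigma_ben <- runif(1, 0.02, 0.3)
  scenario(N,
           additive_selection(sigma_ben,
                              left_effects = runif(I, 0, 0.15),
                              right_effects = runif(J, 0, 0.15),
                              unlinked_effect = runif(1, 0, 0.05), F = F),
           uniform_recombination(I, J, runif(1, 0, 0.01)))
}

two_locus_scenario <- function(N, s00, s01, r01) {
  scenario(N, additive_selection(s00, right_effects = s00 - s01),
           uniform_recombination(0, 1, r01))
}
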