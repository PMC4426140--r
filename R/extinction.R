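#' Extinction probabilities of the multitype branching process
#'
#' While carriers of the beneficial allele are rare they suffer nearly
#' independent fates and the introgression process is a reducible multitype
#' branching process: each class (i,j;f) dies at rate
#' \eqn{1-\sigma_{(i,j;f)}}, reproduces at rate 1, and a birth transmits the
#' full linked block with probability \eqn{1-r_{(i,j)}} or a one-sided
#' truncation (i,k), k < j or (k,j), k < i with probability
#' \eqn{r^{(i,j)}_{(i,k)}} resp. \eqn{r^{(i,j)}_{(k,j)}}; each of the f
#' unlinked alleles is transmitted with probability 1/2. Because
#' recombination with wildtype can only remove alleles, the extinction
#' probability of each class satisfies a scalar quadratic whose other
#' unknowns belong to classes with fewer alleles. Solving these quadratics
#' in order of increasing (i + j), then increasing f, always taking the
#' smaller root, yields the whole table.
#'
#' The smaller root is computed with the cancellation-free quadratic formula
#' (the discriminant can be orders of magnitude below \eqn{b^2} under tight
#' linkage).
#'
#' @param sc a [scenario()].
#' @param residual_tol solved roots must satisfy their quadratic to this
#'   absolute residual.
#' @param bracket_tol slack allowed when checking that a root lies in
#'   \eqn{[0,1]} before clamping.
#' @return An object of class `extinction_table` with elements `Q` (array
#'   over classes), `survival` (`1 - Q`), and the scenario dimensions.
#' @references The establishment probability of the founder class
#'   complements the extinction probability: see
#'   [introgression_probability()].
#' @examples
#' sc <- scenario(10000, additive_selection(0.08))
#' extinction_table(sc)$Q[1, 1, 1] # 0.92
#' @export
extinction_table <- function(sc, residual_tol = 1e-12, bracket_tol = 1e-9) {
  stopifnot(inherits(sc, "scenario"))
  I <- sc$I; J <- sc$J; Fn <- sc$F
  Q <- array(NA_real_, dim = c(I + 1L, J + 1L, Fn + 1L))
  for (ij in 0:(I + J)) {
    for (i in 0:min(ij, I)) {
      j <- ij - i
      if (j > J) next
      rt <- r_total(sc$recombination, i, j)
      rl <- r_targets_left(sc$recombination, i, j)
      rr <- r_targets_right(sc$recombination, i, j)
      for (f in 0:Fn) {
        s <- sigma_of(sc$selection, i, j, f)
        w <- choose(f, 0:f) * 0.5^f      # binomial unlinked transmission
        a <- (1 - rt) * 0.5^f
        b <- -(2 - s)
        for (g in 0:f) {
          mix <- 0
          if (i > 0) mix <- mix + sum(rl * Q[seq_len(i), j + 1L, g + 1L])
          if (j > 0) mix <- mix + sum(rr * Q[i + 1L, seq_len(j), g + 1L])
          b <- b + w[g + 1L] * mix
          if (g < f) b <- b + w[g + 1L] * (1 - rt) * Q[i + 1L, j + 1L, g + 1L]
        }
        cc <- 1 - s
        disc <- b * b - 4 * a * cc
        if (disc < 0)
          stop(sprintf("negative discriminant for class (%d,%d;%d): invalid scenario", i, j, f))
        qf <- -0.5 * (b + sign(b) * sqrt(disc))
        roots <- sort(c(qf / a, cc / qf))
        root <- roots[1L]
        if (root < -bracket_tol || root > 1 + bracket_tol)
          stop(sprintf("extinction probability of class (%d,%d;%d) = %.6g falls outside [0,1]",
                       i, j, f, root))
        resid <- a * root^2 + b * root + cc
        if (abs(resid) > residual_tol * max(1, abs(b)))
          stop(sprintf("root residual %.3g exceeds tolerance for class (%d,%d;%d)",
                       resid, i, j, f))
        Q[i + 1L, j + 1L, f + 1L] <- min(1, max(0, root))
      }
    }
  }
  structure(list(Q = Q, survival = 1 - Q, I = I, J = J, F = Fn),
            class = "extinction_table")
}

#' @export
print.extinction_table <- function(x, ...) {
  cat(sprintf("Extinction table: I = %d, J = %d, F = %d\n", x$I, x$J, x$F))
  cat(sprintf("  Q_(0,0;0) = %.6g, Q_(I,J;F) = %.6g\n",
              x$Q[1, 1, 1], x$Q[x$I + 1, x$J + 1, x$F + 1]))
  invisible(x)
}

#' Introgression probability of the beneficial allele
#'
#' The probability that the beneficial allele, introduced on a single hybrid
#' haplotype of class (I,J;F), escapes stochastic loss and establishes:
#' \eqn{1 - Q_{(I,J;F)}}.
#'
#' @inheritParams extinction_table
#' @param ext optionally a precomputed [extinction_table()].
#' @return A probability.
#' @export
introgression_probability <- function(sc, ext = NULL) {
  if (is.null(ext)) ext <- extinction_table(sc)
  unname(ext$survival[sc$I + 1L, sc$J + 1L, sc$F + 1L])
}

#' Closed forms for up to two unlinked deleterious alleles
#'
#' With no linked deleterious loci the extinction probabilities of the
#' classes carrying f = 0, 1, 2 unlinked alleles have explicit radical
#' solutions:
#' \deqn{Q_0 = 1 - \sigma_0}
#' \deqn{Q_1 = 2 - \sigma_1 - Q_0/2 - \sqrt{(2 - \sigma_1 - Q_0/2)^2 - 2(1-\sigma_1)}}
#' \deqn{Q_2 = 4 - 2\sigma_2 - Q_0/2 - Q_1
#'       - 2\sqrt{(Q_0/4 + Q_1/2 - 2 + \sigma_2)^2 - (1 - \sigma_2)}.}
#'
#' @param sigma0,sigma1,sigma2 class fitnesses for 0, 1, 2 unlinked alleles;
#'   `sigma1`/`sigma2` may be `NA` to request fewer values.
#' @return Named vector with `Q0` and, when requested, `Q1`, `Q2`.
#' @export
closed_form_unlinked <- function(sigma0, sigma1 = NA, sigma2 = NA) {
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  Q0 <- 1 - sigma0
  out <- c(Q0 = Q0)
  if (!is.na(sigma1)) {
    b <- 2 - sigma1 - Q0 / 2
    d <- b^2 - 2 * (1 - sigma1)
    if (d < 0) stop("negative radical argument for Q1")
    Q1 <- b - sqrt(d)
    out <- c(out, Q1 = Q1)
    if (!is.na(sigma2)) {
      h <- Q0 / 4 + Q1 / 2 - 2 + sigma2
      d2 <- h^2 - (1 - sigma2)
      if (d2 < 0) stop("negative radical argument for Q2")
      out <- c(out, Q2 = 4 - 2 * sigma2 - Q0 / 2 - Q1 - 2 * sqrt(d2))
    }
  }
  out
}

#' Closed form for a single linked deleterious allele
#'
#' Extinction probability of the two-locus haplotype (beneficial allele plus
#' one linked deleterious allele at recombination distance `r01`):
#' \deqn{Q_{(0,1)} = \frac{2-\sigma_{(0,1)}-r Q_{(0,0)}
#'   - \sqrt{(2-\sigma_{(0,1)}-r Q_{(0,0)})^2 - 4(1-\sigma_{(0,1)})(1-r)}}
#'   {2(1-r)}} with \eqn{Q_{(0,0)} = 1 - \sigma_{(0,0)}}.
#'
#' Because only single crossover is modelled, at `r01 = 0.5` this equals the
#' unlinked value `Q1` of [closed_form_unlinked()] exactly.
#'
#' @param sigma00 fitness of the clean carrier class, > 0.
#' @param sigma01 fitness of the loaded class.
#' @param r01 recombination probability between the two loci, in [0, 1).
#' @return \eqn{Q_{(0,1)}}.
#' @export
closed_form_single_linked <- function(sigma00, sigma01, r01) {
  if (sigma00 <= 0) stop("sigma00 must be > 0")
  if (r01 < 0 || r01 >= 1) stop("r01 must lie in [0, 1)")
  Q00 <- 1 - sigma00
  b <- 2 - sigma01 - r01 * Q00
  d <- b^2 - 4 * (1 - sigma01) * (1 - r01)
  if (d < 0) stop("negative discriminant")
  (b - sqrt(d)) / (2 * (1 - r01))
}

#' First-order approximation in the recombination probability
#'
#' Linear Taylor expansion of [closed_form_single_linked()] in `r01`, with
#' a different branch depending on the sign of the loaded class fitness:
#' \deqn{Q_{(0,1)} \approx (1-\sigma_{(0,1)})\left(1 -
#'   \frac{\sigma_{(0,0)}-\sigma_{(0,1)}}{\sigma_{(0,1)}} r\right)
#'   \quad (\sigma_{(0,1)} > 0)}
#' \deqn{Q_{(0,1)} \approx 1 + \frac{\sigma_{(0,0)}}{\sigma_{(0,1)}} r
#'   \quad (\sigma_{(0,1)} < 0).}
#' Accuracy degrades as \eqn{\sigma_{(0,1)}} approaches 0.
#'
#' @inheritParams closed_form_single_linked
#' @export
taylor_single_linked <- function(sigma00, sigma01, r01) {
  if (sigma01 == 0) stop("the expansion is undefined at sigma01 = 0")
  if (sigma01 > 0)
    (1 - sigma01) * (1 - (sigma00 - sigma01) / sigma01 * r01)
  else
    1 + sigma00 / sigma01 * r01
}

#' Relative reduction of the introgression probability
#'
#' \eqn{\Delta P = 1 - (1-Q_{with})/(1-Q_{without})}: by how much the extra
#' deleterious material in `scenario_with` reduces the establishment
#' probability relative to the baseline `scenario_without`. Both scenarios
#' must share the clean-carrier fitness \eqn{\sigma_{(0,0;0)}}. For the
#' single-linked-allele configuration the small-`r` and small-cost
#' companion approximations are returned alongside:
#' tight linkage \eqn{\Delta P \approx (s_{del}/\sigma_{(0,0)})(1 -
#' r/\sigma_{(0,1)})} (loaded fitness positive) or
#' \eqn{1 + r/\sigma_{(0,1)}} (negative), loose linkage
#' \eqn{\Delta P \approx s_{del}/(r + \sigma_{(0,0)}(1-r))}, and the
#' unlinked-allele factor \eqn{\approx 2 S_{del}}.
#'
#' @param scenario_with,scenario_without two [scenario()]s sharing
#'   \eqn{\sigma_{(0,0;0)}}.
#' @return List with `delta_P` and a list `approx` of companion values
#'   (entries are `NA` where a formula does not apply).
#' @export
relative_reduction <- function(scenario_with, scenario_without) {
  s00w <- sigma_of(scenario_with$selection, 0, 0, 0)
  s00 <- sigma_of(scenario_without$selection, 0, 0, 0)
  if (abs(s00w - s00) > 1e-12)
    stop("the two scenarios must share sigma_(0,0;0)")
  p_with <- introgression_probability(scenario_with)
  p_without <- introgression_probability(scenario_without)
  if (p_without <= 0) stop("baseline introgression probability is 0")
  out <- list(delta_P = 1 - p_with / p_without,
              approx = list(tight = NA_real_, loose = NA_real_,
                            unlinked_factor = NA_real_))
  if (scenario_with$I == 0 && scenario_with$J == 1 && scenario_with$F == 0 &&
      scenario_without$I + scenario_without$J + scenario_without$F == 0) {
    s01 <- sigma_of(scenario_with$selection, 0, 1, 0)
    r01 <- r_total(scenario_with$recombination, 0, 1)
    s_del <- s00 - s01
    out$approx$tight <- if (s01 > 0)
      s_del / s00 * (1 - r01 / s01) else 1 + r01 / s01
    out$approx$loose <- s_del / (r01 + s00 * (1 - r01))
  }
  if (scenario_with$I + scenario_with$J == 0 && scenario_with$F >= 1 &&
      scenario_without$I + scenario_without$J + scenario_without$F == 0) {
    S_del <- s00 - sigma_of(scenario_with$selection, 0, 0, scenario_with$F)
    out$approx$unlinked_factor <- 2 * S_del
  }
  out
}
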