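test_that("effective initial size is the inverse establishment probability", {
  expect_equal(effective_initial_size(0.01, 0.003), 1 / (0.007 / 0.997))
  expect_equal(effective_initial_size(0.1, 0), 10)
  expect_error(effective_initial_size(0.003, 0.003), "not supercritical")
  expect_error(effective_initial_size(0.001, 0.003), "not supercritical")
})

test_that("logistic sweep frequency starts at nu/N and saturates", {
  sw <- sweep_model(500, 0.01, 0.012, 0.003)
  expect_equal(logistic_frequency(0, sw), sw$nu_bar / 500)
  expect_equal(logistic_frequency(1e6, sw), 1, tolerance = 1e-12)
  t <- seq(0, 2000, by = 50)
  expect_true(all(diff(logistic_frequency(t, sw)) > 0))
  # half-way point of the symmetric logistic
  th <- log((500 - sw$nu_bar) / sw$nu_bar) / 0.01
  expect_equal(logistic_frequency(th, sw), 0.5, tolerance = 1e-12)
})

test_that("escape establishment probability interpolates between its limits", {
  sw <- sweep_model(10000, 0.07, 0.075, 1e-4)
  expect_equal(escape_establishment_probability(0, sw), 0.075,
               tolerance = 5e-2)            # x(0) = nu/N is small but nonzero
  expect_equal(escape_establishment_probability(1e6, sw), 0.075 - 0.07,
               tolerance = 1e-12)
  # at the midpoint the harmonic-type interpolation value holds
  th <- log((10000 - sw$nu_bar) / sw$nu_bar) / 0.07
  expect_equal(escape_establishment_probability(th, sw),
               0.075 * 0.005 / (0.005 * 0.5 + 0.075 * 0.5), tolerance = 1e-10)
})

test_that("single-hitchhiker retention matches quadrature of its integral", {
  integrand <- function(x, N, r, se, st)
    N * r * (1 / se) * st * (st - se) / ((st - se) * (1 - x) + st * x)
  cases <- expand.grid(N = c(500, 10000), se = c(0.01, 0.05),
                       sdel = c(0.002, 0.02), r = c(1e-4, 1e-3))
  for (k in seq_len(nrow(cases))) {
    N <- cases$N[k]; se <- cases$se[k]; st <- se + cases$sdel[k]; r <- cases$r[k]
    sw <- sweep_model(N, se, st, r)
    if (sw$nu_bar >= N / 2) next
    closed <- retention_probability_single(sw)
    quad <- exp(-stats::integrate(integrand, sw$nu_bar / N, 1 - sw$nu_bar / N,
                                  N = N, r = r, se = se, st = st,
                                  rel.tol = 1e-12)$value)
    expect_equal(closed, quad, tolerance = 1e-8)
  }
})

test_that("worked-example retention values and their limits", {
  sw <- sweep_model(500, 0.01, 0.012, 0.003)
  expect_equal(retention_probability_single(sw), 0.795582, tolerance = 1e-6)
  expect_equal(retention_probability_single(sw, use_nu_bar = FALSE),
               0.524645, tolerance = 1e-6)
  # no recombination: nothing can escape
  sw0 <- sweep_model(500, 0.01, 0.012, 1e-300)
  expect_equal(retention_probability_single(sw0), 1, tolerance = 1e-6)
  # nu_bar/N -> 0 recovers the simplified form
  swbig <- sweep_model(1e9, 0.01, 0.012, 0.003,
                       nu_bar = effective_initial_size(0.01, 0.003))
  expect_equal(retention_probability_single(swbig),
               retention_probability_single(swbig, use_nu_bar = FALSE),
               tolerance = 1e-5)
  expect_error(retention_probability_single(sweep_model(100, 0.01, 0.012, 0.003)),
               "N/2")
})

test_that("retention is monotone in Nr and in the fitness gap", {
  ret <- function(N, se, st, r)
    retention_probability_single(sweep_model(N, se, st, r), use_nu_bar = FALSE)
  rs <- c(1e-5, 1e-4, 1e-3)
  expect_true(all(diff(vapply(rs, function(r) ret(1e4, 0.07, 0.075, r),
                              numeric(1))) < 0))
  Ns <- c(1e3, 1e4, 1e5)
  expect_true(all(diff(vapply(Ns, function(N) ret(N, 0.07, 0.075, 1e-4),
                              numeric(1))) < 0))
  s0s <- c(0.072, 0.08, 0.1)   # stronger beneficial allele: more escapes
  expect_true(all(diff(vapply(s0s, function(s0) ret(1e4, 0.07, s0, 1e-4),
                              numeric(1))) < 0))
  s1s <- c(0.05, 0.06, 0.07)   # hitchhiker closer to the beneficial effect
  expect_true(all(diff(vapply(s1s, function(s1) ret(1e4, s1, 0.075, 1e-4),
                              numeric(1))) > 0))
})

test_that("the half-retention recombination distance scales with 1/N", {
  r_half <- function(N) {
    stats::uniroot(function(r)
      retention_probability_single(sweep_model(N, 0.07, 0.075, r),
                                   use_nu_bar = FALSE) - 0.5,
      c(1e-7, 0.05), tol = 1e-12)$root
  }
  expect_equal(r_half(5e3) / r_half(1e4), 2, tolerance = 0.01)
  expect_equal(r_half(1e4) / r_half(4e4), 4, tolerance = 0.01)
})

test_that("multi-hitchhiker retention reduces to known cases", {
  sc <- two_locus_scenario(10000, 0.075, 0.07, 1e-4)
  expect_equal(retention_probability_full(sc, c(0, 1)),
               retention_probability_single(sweep_model(1e4, 0.07, 0.075, 1e-4),
                                            use_nu_bar = FALSE),
               tolerance = 1e-12)
  sc0 <- two_locus_scenario(10000, 0.075, 0.07, 0)
  expect_equal(retention_probability_full(sc0, c(0, 1)), 1)
  # a beneficial-effect linked allele: the clean class is not fitter, so the
  # escape construction does not apply
  expect_error(retention_probability_full(
    scenario(10000, selection_table(matrix(c(0.075, 0.08), 1, 2)),
             uniform_recombination(0, 1, 1e-4)), c(0, 1)),
    "fitter")
})

test_that("Monte-Carlo deterministic phase reproduces the closed form", {
  w <- scenario_fixture("worked_example_10_2")
  row <- det_phase_monte_carlo(w, c(0, 1), reps = 3000, seed = 17)
  closed <- retention_probability_single(sweep_model(500, 0.01, 0.012, 0.003))
  expect_lt(abs(row$P["0,1"] - closed), 3 * row$se["0,1"])
  expect_equal(sum(row$P), 1)
  expect_equal(row$nonconverged, 0)
})

test_that("without escape recombination the established class always fixes", {
  sc <- two_locus_scenario(10000, 0.075, 0.07, 0)
  row <- det_phase_monte_carlo(sc, c(0, 1), reps = 50, seed = 1)
  expect_equal(unname(row$P["0,1"]), 1)
})

test_that("three-hitchhiker retention product agrees with the Monte-Carlo engine", {
  # chain of three linked alleles; the established class is (0,2)
  sc <- scenario(10000,
                 additive_selection(0.075, right_effects = c(0.005, 0.02, 0.065)),
                 uniform_recombination(0, 3, 1e-4))
  closed <- retention_probability_full(sc, c(0, 2), use_nu_bar = TRUE)
  row <- det_phase_monte_carlo(sc, c(0, 2), reps = 3000, seed = 5)
  expect_lt(abs(row$P["0,2"] - closed), 3 * row$se["0,2"] + 0.01)
})
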