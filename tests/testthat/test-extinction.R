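test_that("clean-background establishment equals the selective advantage", {
  sc <- scenario(10000, additive_selection(0.08))
  ext <- extinction_table(sc)
  expect_equal(ext$Q[1, 1, 1], 0.92, tolerance = 1e-12)
  expect_equal(introgression_probability(sc), 0.08, tolerance = 1e-12)
})

test_that("a lethal linked background without recombination blocks introgression", {
  sc <- two_locus_scenario(10000, 0.08, -0.02, 0)
  expect_equal(introgression_probability(sc), 0)
  # loaded founder is certainly lost, yet the clean class keeps sigma_00
  ext <- extinction_table(sc)
  expect_equal(ext$Q[1, 2, 1], 1)
  expect_equal(ext$Q[1, 1, 1], 0.92)
})

test_that("two tightly linked hitch-blockers reproduce the frozen recursion value", {
  sc <- scenario(10000, additive_selection(0.08, right_effects = c(0.01, 0.075)),
                 uniform_recombination(0, 2, 1e-4))
  # frozen from damped fixed-point iteration of the recursion (tol 1e-14)
  expect_equal(introgression_probability(sc), 0.0020616787, tolerance = 1e-6)
})

test_that("quadratic solver agrees with fixed-point iteration on random scenarios", {
  set.seed(101)
  for (rep in 1:8) {
    sc <- random_scenario()
    Q <- extinction_table(sc)$Q
    Qfp <- fp_extinction(sc)
    expect_lt(max(abs(Q - Qfp)), 1e-10)
  }
})

test_that("extinction probabilities are monotone in added deleterious load", {
  base <- scenario(10000, additive_selection(0.06, right_effects = 0.01),
                   uniform_recombination(0, 1, 1e-3))
  more_linked <- scenario(10000,
                          additive_selection(0.06, right_effects = c(0.01, 0.02)),
                          uniform_recombination(0, 2, 1e-3))
  more_unlinked <- scenario(10000,
                            additive_selection(0.06, right_effects = 0.01,
                                               unlinked_effect = 0.02, F = 1),
                            uniform_recombination(0, 1, 1e-3))
  p0 <- introgression_probability(base)
  expect_lte(introgression_probability(more_linked), p0)
  expect_lte(introgression_probability(more_unlinked), p0)
})

test_that("unlinked closed forms match the recursion", {
  cf <- closed_form_unlinked(0.08, 0.07, 0.06)
  expect_equal(unname(cf["Q0"]), 0.92)
  sc <- scenario(10000, selection_table(array(c(0.08, 0.07, 0.06), c(1, 1, 3))),
                 uniform_recombination(0, 0, 0))
  Q <- extinction_table(sc)$Q
  expect_equal(unname(cf["Q1"]), Q[1, 1, 2], tolerance = 1e-12)
  expect_equal(unname(cf["Q2"]), Q[1, 1, 3], tolerance = 1e-12)

  # a costless unlinked allele is invisible to selection
  cf2 <- closed_form_unlinked(0.05, 0.05)
  expect_equal(unname(cf2["Q1"]), unname(cf2["Q0"]), tolerance = 1e-12)
})

test_that("single-linked closed form matches the recursion and its limits", {
  # worked two-locus example: feeds the hitchhiking pipeline
  Q01 <- closed_form_single_linked(0.012, 0.01, 0.003)
  expect_equal(1 - Q01, 0.010442709, tolerance = 1e-7)
  sc <- two_locus_scenario(500, 0.012, 0.01, 0.003)
  expect_equal(Q01, extinction_table(sc)$Q[1, 2, 1], tolerance = 1e-12)

  # r = 0: the pair behaves as one allele of the net effect
  expect_equal(closed_form_single_linked(0.05, 0.02, 0), 1 - 0.02, tolerance = 1e-12)
})

test_that("free recombination reproduces the unlinked closed form exactly", {
  set.seed(7)
  for (rep in 1:50) {
    s00 <- runif(1, 0.01, 0.3)
    s01 <- runif(1, -0.2, s00)
    expect_equal(closed_form_single_linked(s00, s01, 0.5),
                 unname(closed_form_unlinked(s00, s01)["Q1"]),
                 tolerance = 1e-12)
  }
})

test_that("first-order expansion in r matches its two branches", {
  expect_equal(taylor_single_linked(0.05, 0.02, 0), 1 - 0.02)
  expect_equal(taylor_single_linked(0.075, 0.07, 1e-4),
               (1 - 0.07) * (1 - (0.005 / 0.07) * 1e-4))
  expect_equal(taylor_single_linked(0.08, -0.005, 1e-4),
               1 + (0.08 / -0.005) * 1e-4)
  # the expansion tracks the exact value to O(r^2)
  err <- function(r) abs(taylor_single_linked(0.075, 0.07, r) -
                           closed_form_single_linked(0.075, 0.07, r))
  expect_lt(err(1e-4) / err(2e-4), 0.3)
})

test_that("splitting an unlinked cost over several alleles barely matters", {
  # one allele of cost 2s versus two of cost s: deviation is O(s^2)
  dev <- function(s) {
    q1 <- closed_form_unlinked(0.08, 0.08 - 2 * s)["Q1"]
    q2 <- closed_form_unlinked(0.08, 0.08 - s, 0.08 - 2 * s)["Q2"]
    abs((1 - q2) / (1 - q1) - 1)
  }
  expect_lt(dev(0.01) / dev(0.02), 0.3)   # quarters when the cost halves
  # one strong versus many weak alleles of equal total cost (< 1% apart)
  strong <- scenario(10000, additive_selection(0.08, unlinked_effect = 0.04, F = 1))
  weak <- scenario(10000, additive_selection(0.08, unlinked_effect = 0.005, F = 8))
  expect_lt(abs(introgression_probability(strong) /
                  introgression_probability(weak) - 1), 0.01)
})

test_that("relative reduction behaves at its boundaries and approximations", {
  base <- scenario(10000, additive_selection(0.075))
  expect_equal(relative_reduction(base, base)$delta_P, 0)

  blocked <- two_locus_scenario(10000, 0.075, -0.01, 0)
  expect_equal(relative_reduction(blocked, base)$delta_P, 1)

  # tight-linkage companion approximation: error shrinks at least linearly
  # in r and stays far below delta_P itself
  rr1 <- relative_reduction(two_locus_scenario(10000, 0.075, 0.07, 1e-4), base)
  rr2 <- relative_reduction(two_locus_scenario(10000, 0.075, 0.07, 2e-4), base)
  e1 <- abs(rr1$delta_P - rr1$approx$tight)
  e2 <- abs(rr2$delta_P - rr2$approx$tight)
  expect_lt(e1 / e2, 0.55)
  expect_lt(e1, 0.01 * rr1$delta_P)

  expect_error(relative_reduction(blocked,
                                  two_locus_scenario(10000, 0.08, 0.07, 0)),
               "share sigma")
})

test_that("solved roots satisfy their quadratics and stay in [0,1]", {
  set.seed(11)
  for (rep in 1:5) {
    sc <- random_scenario()
    ext <- extinction_table(sc)
    expect_true(all(ext$Q >= 0 & ext$Q <= 1))
  }
})
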