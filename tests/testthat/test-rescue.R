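test_that("own-type establishment probability has the right boundary behaviour", {
  expect_equal(own_type_establishment(0.003, 0.003), 0)
  expect_equal(own_type_establishment(0.05, 0), 0.05)
  expect_equal(own_type_establishment(0.01, 0.003), 0.007 / 0.997)
  # subcritical classes get probability zero, not a negative rate
  expect_equal(own_type_establishment(-0.02, 0.001), 0)
})

test_that("a supercritical founder establishes itself in the plain approximation", {
  sc <- two_locus_scenario(10000, 0.012, 0.01, 1e-4)
  rd <- rescue_distribution(sc, refine_founder = FALSE)
  expect_equal(rd$P[1, 2], 1)
  expect_equal(sum(rd$P), 1)
})

test_that("the refined founder split converges to the delta as r vanishes", {
  for (r in c(1e-3, 1e-4, 1e-5)) {
    sc <- two_locus_scenario(10000, 0.012, 0.01, r)
    rd <- rescue_distribution(sc)
    expect_equal(rd$P[1, 2],
                 conditional_establishment_supercritical(sc) +
                   (1 - conditional_establishment_supercritical(sc)) * 0,
                 tolerance = 1e-12)
  }
  sc0 <- two_locus_scenario(10000, 0.012, 0.01, 1e-7)
  expect_equal(rescue_distribution(sc0)$P[1, 2], 1, tolerance = 1e-3)
})

test_that("a subcritical founder is rescued through its pathways", {
  # two linked alleles, outer one strongly deleterious: the rescue type is
  # (0,0) or (0,1) with weights r (1 - Q) along each pathway
  sc <- scenario(10000, additive_selection(0.075, right_effects = c(0.005, 0.1)),
                 uniform_recombination(0, 2, 1e-4))
  rd <- rescue_distribution(sc)
  expect_equal(sum(rd$P), 1, tolerance = 1e-12)
  expect_equal(rd$P[1, 2], 0.482782, tolerance = 1e-5)  # frozen from the recursion
  expect_equal(rd$P[1, 3], 0)                            # founder cannot establish
  # structure check against the survival-weighted pathway ratio
  ext <- extinction_table(sc)
  expect_equal(rd$P[1, 2],
               ext$survival[1, 2, 1] / (ext$survival[1, 1, 1] + ext$survival[1, 2, 1]),
               tolerance = 1e-12)
})

test_that("only the clean class can rescue when it is the only supercritical one", {
  sc <- scenario(10000, additive_selection(0.05, right_effects = c(0.06)),
                 uniform_recombination(0, 1, 1e-4))
  rd <- rescue_distribution(sc)
  expect_equal(rd$P[1, 1], 1)
})

test_that("rescue is undefined without any recombination pathway", {
  sc <- two_locus_scenario(10000, 0.05, -0.01, 0)
  expect_error(rescue_distribution(sc), "no supercritical haplotype")
})

test_that("rescue distributions normalize across random scenarios", {
  set.seed(23)
  done <- 0
  while (done < 10) {
    sc <- random_scenario()
    rd <- tryCatch(rescue_distribution(sc), error = function(e) NULL)
    if (is.null(rd)) next
    expect_true(all(rd$P >= -1e-15 & rd$P <= 1 + 1e-15))
    expect_equal(sum(rd$P), 1, tolerance = 1e-10)
    # mass sits only on supercritical classes
    for (i in 0:sc$I) for (j in 0:sc$J)
      if (rd$P[i + 1, j + 1] > 0)
        expect_gt(sigma_of(sc$selection, i, j) - r_total(sc$recombination, i, j), 0)
    done <- done + 1
  }
})

test_that("unlinked load is shed before establishment and keeps normalization", {
  sc <- scenario(10000,
                 additive_selection(0.075, right_effects = c(0.005, 0.1),
                                    unlinked_effect = 0.01, F = 3),
                 uniform_recombination(0, 2, 1e-4))
  rd <- rescue_distribution(sc)
  expect_equal(sum(rd$P), 1, tolerance = 1e-10)
  # unlinked alleles barely shift which linked haplotype rescues
  sc0 <- scenario(10000, additive_selection(0.075, right_effects = c(0.005, 0.1)),
                  uniform_recombination(0, 2, 1e-4))
  expect_equal(rd$P[1, 2], rescue_distribution(sc0)$P[1, 2], tolerance = 0.05)
})

test_that("conditional establishment of a supercritical founder", {
  sc <- two_locus_scenario(500, 0.012, 0.01, 0.003)
  p <- conditional_establishment_supercritical(sc)
  expect_equal(p, 0.672341, tolerance = 1e-6)   # frozen from the closed forms

  # no recombination: survival and own-type establishment coincide
  sc0 <- two_locus_scenario(500, 0.012, 0.01, 0)
  expect_equal(conditional_establishment_supercritical(sc0), 1, tolerance = 1e-12)

  # first-order behaviour: 1 - r * sigma00 (1 - sigma01) / sigma01^2
  r <- 1e-5
  scr <- two_locus_scenario(10000, 0.012, 0.01, r)
  expect_equal(conditional_establishment_supercritical(scr),
               1 - r * 0.012 * (1 - 0.01) / 0.01^2, tolerance = 1e-5)

  expect_error(conditional_establishment_supercritical(
    two_locus_scenario(500, 0.05, -0.01, 1e-3)), "not supercritical")
})

test_that("leading-order survival tracks the exact value and warns when crude", {
  # near-critical pathway: the linear term overestimates visibly
  sc <- scenario(10000, additive_selection(0.08, right_effects = c(0.01, 0.075)),
                 uniform_recombination(0, 2, 1e-4))
  expect_warning(v <- survival_leading_order(sc), "overestimates")
  expect_equal(v, 0.0028849, tolerance = 1e-4)  # frozen independent computation

  # vanishing recombination: a subcritical founder cannot be rescued
  sc0 <- scenario(10000, additive_selection(0.08, right_effects = c(0.01, 0.075)),
                  uniform_recombination(0, 2, 1e-9))
  expect_lt(suppressWarnings(survival_leading_order(sc0)), 1e-7)

  expect_error(survival_leading_order(two_locus_scenario(500, 0.05, 0.04, 1e-3)),
               "subcritical")
})
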