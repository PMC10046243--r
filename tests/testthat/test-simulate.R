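test_that("HWE genotype simulation hits the closed-form frequencies", {
  expect_equal(simulateGenotypes(0, 50, seed = 1), rep(0L, 50))
  n <- 100000
  g <- simulateGenotypes(0.33, n, seed = 7)
  freq <- tabulate(g + 1, 3) / n
  hwe <- c(0.67^2, 2 * 0.33 * 0.67, 0.33^2)  # 0.4489 0.4422 0.1089
  se <- sqrt(hwe * (1 - hwe) / n)
  expect_true(all(abs(freq - hwe) < 3 * se))
  expect_identical(g, simulateGenotypes(0.33, n, seed = 7))
  expect_false(identical(g, simulateGenotypes(0.33, n, seed = 8)))
})

test_that("simulated genotypes pass a HWE goodness-of-fit check across seeds", {
  pass <- vapply(1:20, function(s) {
    g <- simulateGenotypes(0.25, 20000, seed = s)
    obs <- tabulate(g + 1, 3)
    exp <- 20000 * c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
    stat <- sum((obs - exp)^2 / exp)
    stat < qchisq(0.95, df = 2)
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("LD pair simulation hits the target r2 and marginal MAFs", {
  pr <- simulateLdPair(0.4, 0.4, r2_target = 0.86, n = 50000, seed = 3)
  expect_equal(ldR2(pr$g1, pr$g2), 0.86, tolerance = 0.02)
  expect_equal(computeMaf(pr$g1), 0.4, tolerance = 0.01)
  expect_equal(computeMaf(pr$g2), 0.4, tolerance = 0.01)

  ind <- simulateLdPair(0.3, 0.45, r2_target = 0, n = 10000, seed = 4)
  expect_lt(ldR2(ind$g1, ind$g2), 0.01)
})

test_that("infeasible LD targets are rejected with the feasibility bound", {
  # D = sqrt(0.9 * 0.05*0.95*0.45*0.55) = 0.1028 > min(p1 q2, q1 p2) = 0.0275
  expect_error(simulateLdPair(0.05, 0.45, r2_target = 0.9, n = 100,
                              seed = 1),
               "infeasible")
  # boundary case remains feasible
  expect_silent(simulateLdPair(0.4, 0.4, r2_target = 1, n = 100,
                               seed = 1))
})

test_that("covariate simulation matches the profile distributions", {
  prof <- cohortProfile("EA")
  cv <- simulateCovariates(prof, n = 100000, seed = 5)
  expect_equal(mean(cv$age), 64.0, tolerance = 3 * 7.7 / sqrt(100000))
  expect_equal(sd(cv$age), 7.7, tolerance = 0.1)
  expect_equal(mean(cv$site), 0.538, tolerance = 0.006)
  expect_true(all(cv$ancestry >= 0 & cv$ancestry <= 1))

  one <- simulateCovariates(list(age_mean = 60, age_sd = 5,
                                 site_prob = 1, ancestry_mean = 0.5,
                                 ancestry_sd = 0), n = 50, seed = 6)
  expect_true(all(one$site == 1))
  expect_equal(one$ancestry, rep(0.5, 50))
})

test_that("intercept calibration solves the marginal prevalence equation", {
  expect_equal(calibrateIntercept(rep(0, 100), 0.5), 0, tolerance = 1e-6)
  expect_equal(calibrateIntercept(rep(0, 100), 0.214), qlogis(0.214),
               tolerance = 1e-6)
  set.seed(8)
  eta <- rnorm(200000)
  b0 <- calibrateIntercept(eta, 0.306)
  expect_equal(mean(plogis(b0 + eta)), 0.306, tolerance = 1e-6)
  y <- sipiScan::simulateOutcome(rep(0L, 200000), rep(0L, 200000), NULL,
                                 NULL, 0.306, seed = 9)
  expect_equal(mean(y), 0.306, tolerance = 3 * sqrt(0.306 * 0.694 / 2e5))
})

test_that("outcome simulation recovers a planted interaction effect", {
  beta <- log(0.59)
  co <- fix_effect_cohort(seed = 21, n = 50000, pattern = "DR_int_or",
                          beta = beta)
  des <- patternDesign("DR_int_or", dosages(co)[1, ], dosages(co)[2, ],
                       covariates(co))
  fit <- fitLogistic(phenotype(co)[des$y_keep], des$X)
  b <- fit$coefficients[["x1x2"]]
  se <- fit$se[["x1x2"]]
  expect_lt(abs(b - beta), 3 * se)
})

test_that("a strong positive interaction is recovered with the right sign", {
  co <- fix_effect_cohort(seed = 22, n = 20000, pattern = "RR_int_oo",
                          beta = log(6.8), maf1 = 0.33, maf2 = 0.32)
  des <- patternDesign("RR_int_oo", dosages(co)[1, ], dosages(co)[2, ],
                       covariates(co))
  fit <- fitLogistic(phenotype(co)[des$y_keep], des$X)
  expect_gt(exp(fit$coefficients[["x1x2"]]), 1)
  expect_lt(fit$wald_p[["x1x2"]], 0.05)
})

test_that("study-profile cohorts reproduce the stratum structure", {
  co <- simulateStudyCohort("EA", seed = 31)
  expect_s4_class(co, "SnpCohort")
  expect_identical(dim(dosages(co)), c(11L, 690L))
  expect_identical(stratumLabel(co), "EA")

  big <- simulateStudyCohort("EA", n = 50000, seed = 32)
  expect_equal(computeMaf(dosages(big)["rs1801133", ]), 0.33,
               tolerance = 0.01)
  expect_equal(ldR2(dosages(big)["rs4644", ], dosages(big)["rs4652", ]),
               0.86, tolerance = 0.02)

  aa <- simulateStudyCohort("AA", seed = 33)
  expect_identical(ncol(aa), 604L)
  expect_equal(mean(phenotype(aa)), 0.306,
               tolerance = 3 * sqrt(0.306 * 0.694 / 604))
  expect_identical(variantInfo(aa)$minor_allele[
    variantInfo(aa)$variant_id == "rs4652"], "A")

  co2 <- simulateStudyCohort("EA", seed = 34)
  expect_false(identical(dosages(co), dosages(co2)))
  expect_identical(dosages(co), dosages(simulateStudyCohort("EA", seed = 31)))
})

test_that("null cohorts keep the fixed-pattern interaction test calibrated", {
  # small type-I spot check; the full calibration sweep lives in the
  # acceptance suite
  rej <- vapply(1:200, function(s) {
    co <- fix_random_cohort(seed = 5000 + s, n = 690, maf1 = 0.33,
                            maf2 = 0.43, prev = 0.214)
    des <- patternDesign("DR_int_or", dosages(co)[1, ],
                         dosages(co)[2, ], covariates(co))
    fit <- fitLogistic(phenotype(co)[des$y_keep], des$X)
    fit$wald_p[["x1x2"]] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("simulation seeds are scoped and do not disturb the caller's RNG", {
  set.seed(123); before <- .Random.seed
  invisible(simulateGenotypes(0.3, 10, seed = 1))
  invisible(simulateStudyCohort("EA", n = 20, seed = 2))
  expect_identical(.Random.seed, before)
})
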