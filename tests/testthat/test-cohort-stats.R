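test_that("computeMaf is dosage sum over 2n non-missing", {
  expect_equal(computeMaf(c(0, 0, 0, 0)), 0)
  expect_equal(computeMaf(c(2, 2)), 1)          # flags need to re-orient
  expect_equal(computeMaf(c(0, 1, 1, 2)), 0.5)
  expect_equal(computeMaf(c(0, 1, NA, NA)), 0.25)
  expect_error(computeMaf(c(NA, NA)), "non-missing")
})

test_that("minor alleles are assigned within the cohort, flipping dosages where needed", {
  # variant 1: A at freq 0.42 stays minor; variant 2: A at 0.84 flips to G
  g1 <- c(rep(2L, 2), rep(1L, 4), rep(0L, 4))        # freq A = 0.40
  g2 <- c(rep(2L, 7), rep(1L, 3), rep(0L, 0))        # freq A = 0.85
  co <- SnpCohort(rbind(rsV1 = g1, rsV2 = g2), fix_variants(2),
                  phenotype = rep(c(0, 1), 5), age = rnorm(10, 64),
                  site = rep(0:1, 5), ancestry = runif(10))
  co <- determineMinorAlleles(co)
  vi <- variantInfo(co)
  expect_equal(vi$minor_allele, c("A", "G"))
  expect_equal(vi$maf, c(0.40, 0.15))
  expect_equal(unname(dosages(co)["rsV2", ]), 2L - g2)
  # idempotent
  co2 <- determineMinorAlleles(co)
  expect_identical(dosages(co2), dosages(co))
  expect_identical(variantInfo(co2)$minor_allele, vi$minor_allele)
})

test_that("frequency ties at 0.5 go to the lexicographically smaller allele", {
  g <- c(0L, 1L, 1L, 2L)  # freq exactly 0.5 for current minor "G"?
  v <- fix_variants(1); v$minor_allele <- "G"   # alleles A/G, G declared
  co <- SnpCohort(matrix(g, 1, dimnames = list("rsV1", NULL)), v,
                  phenotype = c(0, 1, 0, 1), age = rnorm(4, 60),
                  site = c(0, 1, 0, 1), ancestry = runif(4))
  co <- determineMinorAlleles(co)
  expect_equal(variantInfo(co)$minor_allele, "A")
  expect_equal(unname(dosages(co)[1, ]), 2L - g)
})

test_that("monomorphic variants are flagged after orientation", {
  co <- SnpCohort(matrix(0L, 1, 6, dimnames = list("rsV1", NULL)),
                  fix_variants(1), phenotype = rep(c(0, 1), 3),
                  age = rnorm(6, 60), site = rep(0:1, 3),
                  ancestry = runif(6))
  co <- determineMinorAlleles(co)
  expect_true(variantInfo(co)$monomorphic)
})

test_that("after minor-allele assignment every MAF is <= 0.5 (property)", {
  for (s in 1:20) {
    f <- runif(1, 0.05, 0.95)
    g <- sipiScan::simulateGenotypes(min(f, 1 - f), 80, seed = s)
    if (runif(1) < 0.5) g <- 2L - g   # random orientation
    co <- SnpCohort(matrix(as.integer(g), 1,
                           dimnames = list("rsV1", NULL)),
                    fix_variants(1), phenotype = rep_len(c(0, 1), 80),
                    age = rnorm(80, 60), site = rep_len(0:1, 80),
                    ancestry = runif(80))
    co <- determineMinorAlleles(co)
    vi <- variantInfo(co)
    if (!vi$monomorphic) expect_lte(vi$maf, 0.5)
    expect_equal(computeMaf(dosages(co)[1, ]), vi$maf)
  }
})

test_that("LD r2: perfect correlation and anticorrelation give 1; independence gives ~0", {
  expect_equal(ldR2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ldR2(c(0, 0, 1, 2), c(2, 2, 1, 0)), 1)
  g1 <- simulateGenotypes(0.3, 10000, seed = 11)
  g2 <- simulateGenotypes(0.4, 10000, seed = 12)
  expect_lt(ldR2(g1, g2), 0.01)
})

test_that("LD r2 is symmetric, flip-invariant and handles missing/degenerate input", {
  for (s in 1:10) {
    g1 <- simulateGenotypes(0.25, 60, seed = s)
    g2 <- simulateGenotypes(0.45, 60, seed = s + 50)
    g1[1:3] <- NA
    r <- ldR2(g1, g2)
    expect_equal(ldR2(g2, g1), r)
    expect_equal(ldR2(2 - g1, g2), r)
    expect_equal(ldR2(g1, 2 - g2), r)
  }
  expect_warning(r0 <- ldR2(rep(1, 10), simulateGenotypes(0.3, 10, 1)),
                 "variance")
  expect_true(is.na(r0))
})

test_that("genotype distributions tally categories and chi-square matches a hand oracle", {
  d <- genotypeDistribution(c(0, 0, 1, 2, NA, 1, 1))
  expect_equal(unname(d), c(2L, 3L, 1L, 1L))
  expect_equal(sum(d[1:3]), 6L)

  same <- compareDistributions(c(hom_major = 30, het = 50, hom_minor = 20),
                               c(hom_major = 30, het = 50, hom_minor = 20))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- compareDistributions(c(hom_major = 50, het = 0, hom_minor = 0),
                              c(hom_major = 0, het = 0, hom_minor = 50))
  expect_lt(sep$p.value, 0.001)

  # hand-computed Pearson statistic on random small tables
  set.seed(99)
  for (i in 1:10) {
    a <- c(hom_major = sample(5:50, 1), het = sample(5:50, 1),
           hom_minor = sample(5:50, 1))
    b <- c(hom_major = sample(5:50, 1), het = sample(5:50, 1),
           hom_minor = sample(5:50, 1))
    res <- compareDistributions(a, b)
    expect_equal(res$statistic, oracle_chisq(rbind(a, b)),
                 tolerance = 1e-10)
  }
  ex <- compareDistributions(c(hom_major = 30, het = 50, hom_minor = 20),
                             c(hom_major = 45, het = 40, hom_minor = 15))
  expect_equal(ex$statistic,
               oracle_chisq(rbind(c(30, 50, 20), c(45, 40, 15))),
               tolerance = 1e-10)
})

test_that("empty-in-both genotype categories collapse before testing", {
  res <- compareDistributions(c(hom_major = 30, het = 20, hom_minor = 0),
                              c(hom_major = 25, het = 30, hom_minor = 0))
  expect_equal(res$df, 1L)
  expect_error(
    compareDistributions(c(hom_major = 10, het = 0, hom_minor = 0),
                         c(hom_major = 20, het = 0, hom_minor = 0)),
    "categories")
})

test_that("aggressiveness classification matches the clinical rule", {
  expect_equal(classifyAggressiveness(8, 4, "T2"), "high")
  expect_equal(classifyAggressiveness(6, 5, "T1"), "low")
  expect_equal(classifyAggressiveness(7, 5, "T3"), "high")
  expect_equal(classifyAggressiveness(6, 15, "T2"), "intermediate")
  expect_equal(classifyAggressiveness(5, 25, "T1"), "high")   # PSA > 20
  expect_equal(classifyAggressiveness(5, 20, "T1"), "intermediate") # strict >
  expect_equal(classifyAggressiveness(6, 10, "T1"), "intermediate") # strict <
  expect_equal(classifyAggressiveness(7, 5, "T2"), "intermediate")
  expect_error(classifyAggressiveness(6, NA, "T1"), "non-missing")
  expect_error(classifyAggressiveness(6, 5, "T5"), "stage")
})

test_that("the classification partitions the full grid into exactly one category", {
  grid <- expand.grid(gleason = 2:10,
                      stage = c("T1", "T2", "T3", "T4"),
                      psa = c(0, 5, 9.99, 10, 15, 20, 20.01, 50),
                      stringsAsFactors = FALSE)
  cls <- classifyAggressiveness(grid$gleason, grid$psa, grid$stage)
  expect_true(all(cls %in% c("high", "intermediate", "low")))
  # rule re-derived independently per row
  manual <- apply(grid, 1, function(r) {
    gl <- as.numeric(r["gleason"]); ps <- as.numeric(r["psa"])
    st <- r["stage"]
    if (gl >= 8 || ps > 20 || (gl >= 7 && st %in% c("T3", "T4")))
      "high"
    else if (gl < 7 && st %in% c("T1", "T2") && ps < 10) "low"
    else "intermediate"
  })
  expect_equal(cls, unname(manual))
})
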