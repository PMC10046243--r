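#' Load a bundled or custom cohort generation profile
#'
#' Profiles bundle the generative parameters of one stratum: sample size,
#' target high-aggressiveness prevalence, per-variant minor allele
#' frequencies (with variant metadata), covariate distributions (age
#' mean/SD in years, probability of the Louisiana site, ancestry-proportion
#' mean/SD) and an optional linkage-disequilibrium pair. Two profiles ship
#' with the package, emulating the European-American ("EA": n = 690,
#' prevalence 21.4\%) and African-American ("AA": n = 604, prevalence
#' 30.6\%) prostate-cancer patient strata of the folate-pathway candidate
#' panel, including the strong EA LD pair rs4644-rs4652 (r^2 = 0.86) and
#' the race-reversed minor alleles of rs4652 and the DHFR 19-bp del/ins.
#'
#' @param stratum "EA", "AA", or a path to a YAML profile file.
#' @return list with elements \code{stratum}, \code{n},
#'   \code{target_prevalence}, \code{age_mean}, \code{age_sd},
#'   \code{site_prob}, \code{ancestry_mean}, \code{ancestry_sd},
#'   \code{ld} (NULL or list(variant_1, variant_2, r2)) and
#'   \code{variants} (data.frame with variant_id, chromosome, position,
#'   gene, allele_a, allele_b, minor_allele, maf).
#' @export
cohortProfile <- function(stratum = c("EA", "AA")) {
  path <- if (file.exists(stratum[1])) stratum[1] else {
    stratum <- match.arg(stratum)
    system.file("extdata", "profiles",
                paste0(tolower(stratum), ".yaml"),
                package = "sipiScan", mustWork = TRUE)
  }
  prof <- yaml::read_yaml(path)
  prof$n <- prof$n_samples
  prof$variants <- do.call(rbind, lapply(prof$variants, function(v)
    data.frame(v, stringsAsFactors = FALSE)))
  if (is.null(prof$variants$position))
    prof$variants$position <- NA_integer_
  stopifnot(prof$target_prevalence > 0, prof$target_prevalence < 1,
            prof$n >= 1, all(prof$variants$maf > 0),
            all(prof$variants$maf <= 0.5))
  prof
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' i.i.d. dosage draws with P(0) = (1-p)^2, P(1) = 2p(1-p), P(2) = p^2
#' where p is the minor allele frequency.
#'
#' @param maf minor allele frequency in [0, 0.5].
#' @param n sample count.
#' @param seed integer seed.
#' @return integer dosage vector of length n.
#' @export
simulateGenotypes <- function(maf, n, seed) {
  stopifnot(maf >= 0, maf <= 0.5, n >= 1)
  .withSeed(seed, {
    p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    sample(0:2, n, replace = TRUE, prob = p)
  })
}

#' Simulate a pair of variants in linkage disequilibrium
#'
#' Draws 2n haplotypes from the four-haplotype distribution implied by the
#' two minor allele frequencies and the coupling D = r * sqrt(p1 q1 p2 q2)
#' with r = sqrt(r2_target) > 0, then pairs haplotypes into genotypes, so
#' the expected dosage r^2 equals the target. The target is feasible only
#' when D <= min(p1 (1-p2), p2 (1-p1)) (all four haplotype frequencies
#' non-negative); infeasible targets raise an error reporting the bound.
#'
#' @param maf1,maf2 minor allele frequencies in (0, 0.5].
#' @param r2_target desired dosage r^2 in [0, 1].
#' @param n sample count.
#' @param seed integer seed.
#' @return list with integer dosage vectors \code{g1}, \code{g2}.
#' @export
simulateLdPair <- function(maf1, maf2, r2_target, n, seed) {
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            r2_target >= 0, r2_target <= 1, n >= 1)
  q1 <- 1 - maf1; q2 <- 1 - maf2
  D <- sqrt(r2_target) * sqrt(maf1 * q1 * maf2 * q2)
  bound <- min(maf1 * q2, maf2 * q1)
  if (D > bound + 1e-12) {
    maxR2 <- (bound / sqrt(maf1 * q1 * maf2 * q2))^2
    stop(sprintf(
      "r2_target %.3f infeasible for MAFs (%.3f, %.3f): D = %.4f exceeds %.4f (max r2 = %.3f)",
      r2_target, maf1, maf2, D, bound, maxR2))
  }
  # haplotypes over (minor1, minor2): 11, 10, 01, 00
  hap <- c(maf1 * maf2 + D, maf1 * q2 - D, q1 * maf2 - D, q2 * q1 + D)
  hap <- pmax(hap, 0); hap <- hap / sum(hap)
  .withSeed(seed, {
    draws <- sample.int(4, 2 * n, replace = TRUE, prob = hap)
    a1 <- as.integer(draws %in% c(1, 2))  # carries minor at locus 1
    a2 <- as.integer(draws %in% c(1, 3))
    idx <- matrix(seq_len(2 * n), nrow = 2)
    list(g1 = a1[idx[1, ]] + a1[idx[2, ]],
         g2 = a2[idx[1, ]] + a2[idx[2, ]])
  })
}

#' Simulate adjustment covariates for one stratum
#'
#' Age ~ Normal(age_mean, age_sd); site ~ Bernoulli(site_prob)
#' (1 = Louisiana); ancestry ~ Normal(ancestry_mean, ancestry_sd)
#' truncated to [0, 1] by rejection.
#'
#' @param profile a cohort profile (see \code{\link{cohortProfile}}).
#' @param n sample count (default \code{profile$n}).
#' @param seed integer seed.
#' @return data.frame with columns age, site, ancestry.
#' @export
simulateCovariates <- function(profile, n = profile$n, seed) {
  .withSeed(seed, {
    age <- stats::rnorm(n, profile$age_mean, profile$age_sd)
    site <- stats::rbinom(n, 1, profile$site_prob)
    anc <- stats::rnorm(n, profile$ancestry_mean, profile$ancestry_sd)
    if (profile$ancestry_sd > 0) {
      bad <- which(anc < 0 | anc > 1)
      while (length(bad)) {
        anc[bad] <- stats::rnorm(length(bad), profile$ancestry_mean,
                                 profile$ancestry_sd)
        bad <- bad[anc[bad] < 0 | anc[bad] > 1]
      }
    }
    data.frame(age = age, site = site, ancestry = anc)
  })
}

#' Calibrate the logistic intercept to a marginal prevalence
#'
#' Solves mean(plogis(b0 + eta)) = target over the supplied sample of
#' linear predictors by monotone root finding, to within 1e-6 on the
#' prevalence scale. Calibration is marginal (population-average), so the
#' realized prevalence matches the target up to binomial noise whatever
#' the eta distribution.
#'
#' @param eta numeric vector of linear-predictor values (excluding the
#'   intercept).
#' @param target_prevalence target in (0, 1).
#' @return the intercept b0.
#' @export
calibrateIntercept <- function(eta, target_prevalence) {
  stopifnot(all(is.finite(eta)), target_prevalence > 0,
            target_prevalence < 1)
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target_prevalence
  lo <- -50; hi <- 50
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Interaction effect specification for outcome simulation
#'
#' @param pattern pattern label (e.g. "DR_int_or") or single-row pattern
#'   data.frame; the genotype codings of the generating model.
#' @param beta_interaction log-odds of the product term (e.g.
#'   \code{log(0.59)}).
#' @param beta_main_1,beta_main_2 main-effect log-odds (0 for
#'   interaction-only generation).
#' @param covariate_betas named log-odds for age, site, ancestry
#'   (default all 0).
#' @return list of class \code{"effectSpec"}.
#' @export
effectSpec <- function(pattern, beta_interaction,
                       beta_main_1 = 0, beta_main_2 = 0,
                       covariate_betas = c(age = 0, site = 0,
                                           ancestry = 0)) {
  if (is.character(pattern)) pattern <- patternByLabel(pattern)
  stopifnot(is.finite(beta_interaction), is.finite(beta_main_1),
            is.finite(beta_main_2), all(is.finite(covariate_betas)))
  structure(list(pattern = pattern,
                 beta_interaction = beta_interaction,
                 beta_main_1 = beta_main_1, beta_main_2 = beta_main_2,
                 covariate_betas = covariate_betas),
            class = "effectSpec")
}

#' Simulate a binary outcome from genotypes, covariates and an effect
#'
#' y ~ Bernoulli(plogis(b0 + b1 x1 + b2 x2 + b3 x1 x2 + covariate terms))
#' with x1, x2 coded per the effect's pattern (modes and directions) and
#' b0 calibrated so the marginal prevalence matches the target.
#'
#' @param g1,g2 dosage vectors of the two interacting variants.
#' @param covariateData data.frame with age, site, ancestry (or NULL).
#' @param effect an \code{\link{effectSpec}}, or NULL for a pure-null
#'   outcome (independent of genotypes and covariates).
#' @param target_prevalence marginal prevalence in (0, 1).
#' @param seed integer seed.
#' @return 0/1 phenotype vector.
#' @export
simulateOutcome <- function(g1, g2, covariateData, effect,
                            target_prevalence, seed) {
  n <- length(g1)
  eta <- rep(0, n)
  if (!is.null(effect)) {
    p <- effect$pattern
    x1 <- codeGenotype(g1, p$mode1, p$dir1)
    x2 <- codeGenotype(g2, p$mode2, p$dir2)
    eta <- effect$beta_main_1 * x1 + effect$beta_main_2 * x2 +
      effect$beta_interaction * x1 * x2
    if (!is.null(covariateData)) {
      cb <- effect$covariate_betas
      for (nm in names(cb))
        if (cb[[nm]] != 0) eta <- eta + cb[[nm]] * covariateData[[nm]]
    }
  }
  b0 <- calibrateIntercept(eta, target_prevalence)
  .withSeed(seed, stats::rbinom(n, 1, stats::plogis(b0 + eta)))
}

#' Simulate a full study-like cohort for one stratum
#'
#' Generates the complete \linkS4class{SnpCohort} a profile describes:
#' Hardy-Weinberg genotypes at the profile MAFs (mutually independent
#' except the declared LD pair), covariates, and a logistic outcome. With
#' \code{effect = NULL} the outcome is independent of the genotypes (null
#' cohort) at the profile's marginal prevalence.
#'
#' @param stratum "EA", "AA", a profile path, or a profile list.
#' @param effect optional \code{\link{effectSpec}}; its pattern's variants
#'   must name two profile variants via \code{effect_pair}.
#' @param effect_pair character(2): the variant ids the effect applies to
#'   (default: the first two profile variants when an effect is given).
#' @param n override the profile sample size.
#' @param seed base integer seed; per-variant, covariate and outcome
#'   substreams are derived deterministically from it.
#' @return a \linkS4class{SnpCohort}.
#' @export
simulateStudyCohort <- function(stratum = "EA", effect = NULL,
                                effect_pair = NULL, n = NULL, seed = 1) {
  prof <- if (is.list(stratum)) stratum else cohortProfile(stratum)
  if (is.null(n)) n <- prof$n
  v <- prof$variants
  k <- nrow(v)
  dosage <- matrix(NA_integer_, nrow = k, ncol = n,
                   dimnames = list(v$variant_id, NULL))
  ldIdx <- integer(0)
  if (!is.null(prof$ld)) {
    ldIdx <- match(c(prof$ld$variant_1, prof$ld$variant_2), v$variant_id)
    if (any(is.na(ldIdx))) stop("LD pair variants not in profile")
    pair <- simulateLdPair(v$maf[ldIdx[1]], v$maf[ldIdx[2]],
                           prof$ld$r2, n, deriveSeed(seed, 1000))
    dosage[ldIdx[1], ] <- pair$g1
    dosage[ldIdx[2], ] <- pair$g2
  }
  for (i in setdiff(seq_len(k), ldIdx))
    dosage[i, ] <- simulateGenotypes(v$maf[i], n, deriveSeed(seed, i))
  cv <- simulateCovariates(prof, n, deriveSeed(seed, 2000))
  if (is.null(effect)) {
    y <- simulateOutcome(dosage[1, ], dosage[2, ], cv, NULL,
                         prof$target_prevalence, deriveSeed(seed, 3000))
  } else {
    if (is.null(effect_pair)) effect_pair <- v$variant_id[1:2]
    ei <- match(effect_pair, v$variant_id)
    if (any(is.na(ei))) stop("effect_pair variants not in profile")
    y <- simulateOutcome(dosage[ei[1], ], dosage[ei[2], ], cv, effect,
                         prof$target_prevalence, deriveSeed(seed, 3000))
  }
  SnpCohort(dosage, v, phenotype = y, age = cv$age, site = cv$site,
            ancestry = cv$ancestry, stratum = prof$stratum)
}
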