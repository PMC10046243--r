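#' Minor allele frequency from a dosage vector
#'
#' MAF = (sum of minor-allele dosages) / (2 x number of non-missing
#' genotypes). A value above 0.5 indicates the dosages are oriented to the
#' major allele and the variant needs re-orientation
#' (see \code{\link{determineMinorAlleles}}).
#'
#' @param dosages numeric vector of dosages in \{0,1,2\}, NA = missing.
#' @return frequency in [0, 1].
#' @export
computeMaf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("no non-missing genotypes")
  sum(d) / (2 * length(d))
}

#' Assign cohort-specific minor alleles and re-orient dosages
#'
#' The minor allele is defined within the analyzed stratum: for each variant
#' the allele with frequency <= 0.5 becomes the minor allele, and dosages are
#' flipped (g -> 2 - g) wherever the current orientation counts the major
#' allele. A frequency of exactly 0.5 is broken toward the lexicographically
#' smaller allele label. Monomorphic variants (frequency 0 after
#' orientation) are flagged in \code{rowData(x)$monomorphic}; downstream
#' models must exclude them. Idempotent.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @return the cohort with updated dosages, \code{minor_allele}, \code{maf}
#'   and \code{monomorphic} columns.
#' @export
determineMinorAlleles <- function(cohort) {
  d <- dosages(cohort)
  rd <- SummarizedExperiment::rowData(cohort)
  for (i in seq_len(nrow(d))) {
    g <- d[i, ]
    if (all(is.na(g))) stop("variant ", rownames(d)[i], " is fully missing")
    f <- computeMaf(g)
    cur <- rd$minor_allele[i]
    other <- setdiff(c(rd$allele_a[i], rd$allele_b[i]), cur)
    flip <- f > 0.5
    if (f == 0.5) {
      # tie: minor allele is the lexicographically smaller label
      flip <- other < cur
    }
    if (flip) {
      d[i, ] <- 2L - g
      rd$minor_allele[i] <- other
      f <- 1 - f
    }
    rd$maf[i] <- f
    rd$monomorphic[i] <- f == 0 || f == 1
  }
  SummarizedExperiment::assay(cohort, "dosage") <- d
  SummarizedExperiment::rowData(cohort) <- rd
  methods::validObject(cohort)
  cohort
}

#' Composite (dosage-based) linkage disequilibrium r-squared
#'
#' Squared Pearson correlation between two dosage vectors, with pairwise
#' deletion of missing values. Invariant to flipping either vector's
#' orientation (g -> 2 - g) and symmetric in its arguments.
#'
#' @param dosages1,dosages2 dosage vectors of equal length.
#' @return r-squared in [0, 1]; \code{NA} with a warning if fewer than two
#'   pairwise-complete observations or either vector is constant.
#' @export
ldR2 <- function(dosages1, dosages2) {
  ok <- !is.na(dosages1) & !is.na(dosages2)
  x <- dosages1[ok]; y <- dosages2[ok]
  if (length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0) {
    warning("LD r^2 undefined: fewer than 2 complete pairs or zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Genotype category counts
#'
#' Tallies dosages into the three genotype categories: homozygous major
#' (0), heterozygous (1), homozygous minor (2), plus a missing count.
#'
#' @param dosages dosage vector.
#' @return named integer vector with elements \code{hom_major},
#'   \code{het}, \code{hom_minor}, \code{missing}.
#' @export
genotypeDistribution <- function(dosages) {
  c(hom_major = sum(dosages == 0, na.rm = TRUE),
    het       = sum(dosages == 1, na.rm = TRUE),
    hom_minor = sum(dosages == 2, na.rm = TRUE),
    missing   = sum(is.na(dosages)))
}

#' Compare two genotype distributions by Pearson chi-square
#'
#' Tests whether two groups (e.g. race strata) have the same genotype
#' distribution over the three categories. Categories empty in both groups
#' are collapsed out before testing. Applied without continuity correction
#' so the statistic is the plain Pearson chi-square.
#'
#' @param d1,d2 outputs of \code{\link{genotypeDistribution}} (the
#'   \code{missing} element, if present, is ignored).
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
compareDistributions <- function(d1, d2) {
  cats <- c("hom_major", "het", "hom_minor")
  x1 <- d1[cats]; x2 <- d2[cats]
  keep <- (x1 + x2) > 0
  if (sum(keep) < 2) stop("fewer than 2 non-empty genotype categories")
  tab <- rbind(x1[keep], x2[keep])
  if (identical(unname(tab[1, ] / sum(tab[1, ])),
                unname(tab[2, ] / sum(tab[2, ])))) {
    # identical distributions: chi-square 0 by construction
    return(list(statistic = 0, df = ncol(tab) - 1L, p.value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Classify prostate cancer aggressiveness
#'
#' Clinical three-level classification from Gleason score, PSA and clinical
#' T-stage: high aggressive if Gleason >= 8, or PSA > 20 ng/mL, or
#' (Gleason >= 7 and stage T3-T4); low aggressive if Gleason < 7 and stage
#' T1-T2 and PSA < 10 ng/mL; intermediate otherwise. Boundaries are strict
#' as stated (PSA exactly 20 is not high; PSA exactly 10 is not low).
#'
#' @param gleason integer Gleason score in [2, 10].
#' @param psa PSA in ng/mL, >= 0.
#' @param stage clinical T-stage, one of "T1", "T2", "T3", "T4".
#' @return "high", "intermediate" or "low". Vectorised.
#' @export
classifyAggressiveness <- function(gleason, psa, stage) {
  n <- max(length(gleason), length(psa), length(stage))
  gleason <- rep_len(gleason, n); psa <- rep_len(psa, n)
  stage <- rep_len(stage, n)
  if (any(is.na(gleason) | is.na(psa) | is.na(stage)))
    stop("gleason, psa and stage must all be non-missing")
  if (!all(stage %in% c("T1", "T2", "T3", "T4")))
    stop("stage must be one of T1-T4")
  if (any(gleason < 2 | gleason > 10)) stop("gleason must be in [2, 10]")
  if (any(psa < 0)) stop("psa must be >= 0")
  high <- gleason >= 8 | psa > 20 | (gleason >= 7 & stage %in% c("T3", "T4"))
  low <- gleason < 7 & stage %in% c("T1", "T2") & psa < 10
  out <- rep("intermediate", n)
  out[low] <- "low"
  out[high] <- "high"   # high takes precedence over low (disjoint anyway)
  out
}
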