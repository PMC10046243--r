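#' Single-variant association under three inheritance modes
#'
#' Fits the covariate-adjusted logistic model for one variant under each of
#' the additive, dominant and recessive codings (minor-allele based), and
#' selects the best mode as the one with the smallest Wald p-value of the
#' genotype term. A mode whose coding is constant in the analyzed samples
#' (e.g. recessive with no minor-allele homozygotes) is excluded and the
#' exclusion recorded. Ties in p are broken in the fixed order
#' additive > dominant > recessive.
#'
#' @param cohort a \linkS4class{SnpCohort} (after
#'   \code{\link{determineMinorAlleles}}).
#' @param variant_id variant to test.
#' @param adjust logical; include the age/site/ancestry covariates
#'   (default TRUE).
#' @return list: \code{variant_id}, \code{fits} (per-mode
#'   \code{logisticFit} or exclusion reason string), \code{best_mode},
#'   \code{best_or}, \code{best_ci} (length-2), \code{best_p},
#'   \code{excluded} (character vector of excluded modes).
#' @export
snpAssociation <- function(cohort, variant_id, adjust = TRUE) {
  g <- .variantDosage(cohort, variant_id)
  y <- phenotype(cohort)
  cv <- if (adjust) covariates(cohort) else NULL
  keep <- !is.na(g) & !is.na(y)
  if (!is.null(cv)) keep <- keep & stats::complete.cases(cv)
  modes <- c("additive", "dominant", "recessive")
  fits <- list(); pvals <- c()
  for (m in modes) {
    x <- codeGenotype(g[keep], m)
    if (length(unique(x)) < 2) {
      fits[[m]] <- paste0("excluded: constant ", m, " coding")
      next
    }
    X <- cbind(`(Intercept)` = 1, snp = x)
    if (!is.null(cv)) X <- cbind(X, as.matrix(cv[keep, , drop = FALSE]))
    fit <- tryCatch(fitLogistic(y[keep], X), error = function(e) e)
    if (inherits(fit, "error")) {
      fits[[m]] <- paste0("excluded: ", conditionMessage(fit))
      next
    }
    fits[[m]] <- fit
    pvals[m] <- fit$wald_p[["snp"]]
  }
  excluded <- modes[!modes %in% names(pvals)]
  if (!length(pvals))
    return(list(variant_id = variant_id, fits = fits, best_mode = NA,
                best_or = NA, best_ci = c(NA, NA), best_p = NA,
                excluded = excluded))
  # stable min: ties resolved by the additive > dominant > recessive order
  best <- names(pvals)[which.min(pvals)]
  orci <- termOddsRatio(fits[[best]], "snp")
  list(variant_id = variant_id, fits = fits, best_mode = best,
       best_or = unname(orci["or"]),
       best_ci = unname(orci[c("ci_low", "ci_high")]),
       best_p = unname(orci["p"]), excluded = excluded)
}

#' Single-variant association scan over all variants
#'
#' Runs \code{\link{snpAssociation}} for every non-monomorphic variant and
#' assembles the per-variant best-mode table (variant, gene, minor/major
#' alleles, MAF, selected mode, OR, CI, p).
#'
#' @inheritParams snpAssociation
#' @return data.frame, one row per variant, sorted as in the cohort.
#' @export
singleSnpScan <- function(cohort, adjust = TRUE) {
  vi <- variantInfo(cohort)
  rows <- lapply(seq_len(nrow(vi)), function(i) {
    v <- vi$variant_id[i]
    if (isTRUE(vi$monomorphic[i])) {
      return(data.frame(variant_id = v, gene = vi$gene[i],
                        minor_allele = vi$minor_allele[i],
                        major_allele = setdiff(c(vi$allele_a[i],
                                                 vi$allele_b[i]),
                                               vi$minor_allele[i])[1],
                        maf = vi$maf[i], mode = NA, or = NA,
                        ci_low = NA, ci_high = NA, p = NA,
                        note = "monomorphic", stringsAsFactors = FALSE))
    }
    res <- snpAssociation(cohort, v, adjust = adjust)
    data.frame(variant_id = v, gene = vi$gene[i],
               minor_allele = vi$minor_allele[i],
               major_allele = setdiff(c(vi$allele_a[i], vi$allele_b[i]),
                                      vi$minor_allele[i])[1],
               maf = vi$maf[i],
               mode = res$best_mode, or = res$best_or,
               ci_low = res$best_ci[1], ci_high = res$best_ci[2],
               p = res$best_p,
               note = if (length(res$excluded))
                 paste("excluded:", paste(res$excluded, collapse = ","))
               else "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' alpha / m. Summaries render the threshold rounded to four decimals
#' (0.05/11 = 0.0045, 0.05/55 = 0.0009); comparisons should use the
#' unrounded value.
#'
#' @param m number of tests, >= 1.
#' @param alpha family-wise level, default 0.05.
#' @return the unrounded threshold, with attribute \code{"rendered"}
#'   giving the 4-decimal display value.
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  thr <- alpha / m
  attr(thr, "rendered") <- round(thr, 4)
  thr
}
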