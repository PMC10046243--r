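#' Scan one variant pair over the 45-pattern catalogue
#'
#' Fits every fittable pattern from \code{\link{interactionPatterns}} for
#' the pair (each model adjusted for the cohort covariates), computes each
#' model's BIC, and selects the pattern with the lowest BIC. BIC values
#' within 1e-7 of the minimum are treated as tied (interaction-only
#' codings that induce the same two-group partition of the 3x3 genotype
#' grid are numerically identical models); ties are broken by fewer
#' estimated parameters, then by catalogue order. The reported odds ratio,
#' 95\% CI and p-value belong to the selected model's product term.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @param variant_1,variant_2 variant ids.
#' @param adjust include covariates (default TRUE).
#' @return list of class \code{"pairResult"}: \code{variant_1},
#'   \code{variant_2}, \code{pattern} (selected label),
#'   \code{interaction_or}, \code{ci_low}, \code{ci_high}, \code{p_pair},
#'   \code{bic_selected}, \code{n_used}, \code{bics} (named vector over
#'   the 45 labels, NA where unfittable), \code{skipped} (named reasons).
#' @export
scanPair <- function(cohort, variant_1, variant_2, adjust = TRUE) {
  g1 <- .variantDosage(cohort, variant_1)
  g2 <- .variantDosage(cohort, variant_2)
  y <- phenotype(cohort)
  cv <- if (adjust) covariates(cohort) else NULL
  okY <- !is.na(y)
  cat45 <- interactionPatterns()
  bics <- stats::setNames(rep(NA_real_, nrow(cat45)), cat45$label)
  kvec <- bics
  fits <- vector("list", nrow(cat45)); names(fits) <- cat45$label
  skipped <- character(0)
  for (i in seq_len(nrow(cat45))) {
    lab <- cat45$label[i]
    des <- patternDesign(cat45[i, ], ifelse(okY, g1, NA),
                         ifelse(okY, g2, NA), cv)
    if (!des$fittable) { skipped[lab] <- des$reason; next }
    fit <- tryCatch(fitLogistic(y[which(des$y_keep)], des$X),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[lab] <- conditionMessage(fit); next
    }
    if (!fit$converged) { skipped[lab] <- "did not converge"; next }
    if (is.na(fit$coefficients[[des$product_col]])) {
      skipped[lab] <- "product term aliased"; next
    }
    fits[[lab]] <- fit
    bics[lab] <- bicOf(fit)
    kvec[lab] <- fit$k
  }
  if (all(is.na(bics)))
    return(structure(list(variant_1 = variant_1, variant_2 = variant_2,
                          pattern = NA_character_, interaction_or = NA,
                          ci_low = NA, ci_high = NA, p_pair = NA,
                          bic_selected = NA, n_used = NA, bics = bics,
                          skipped = skipped), class = "pairResult"))
  tie_tol <- 1e-7
  minB <- min(bics, na.rm = TRUE)
  cand <- which(!is.na(bics) & bics <= minB + tie_tol)
  cand <- cand[order(kvec[cand], cand)]   # fewer params, then order
  sel <- names(bics)[cand[1]]
  fit <- fits[[sel]]
  orci <- termOddsRatio(fit, "x1x2")
  structure(list(
    variant_1 = variant_1, variant_2 = variant_2, pattern = sel,
    interaction_or = unname(orci["or"]), ci_low = unname(orci["ci_low"]),
    ci_high = unname(orci["ci_high"]), p_pair = unname(orci["p"]),
    bic_selected = unname(bics[sel]), n_used = fit$n_used,
    bics = bics, skipped = skipped), class = "pairResult")
}

#' @export
print.pairResult <- function(x, ...) {
  cat(x$variant_1, "x", x$variant_2, "->", x$pattern,
      sprintf("OR %.2f (%.2f, %.2f) p=%.3g BIC=%.2f n=%d\n",
              x$interaction_or, x$ci_low, x$ci_high, x$p_pair,
              x$bic_selected, x$n_used))
  invisible(x)
}

#' All-pairs interaction scan
#'
#' Runs \code{\link{scanPair}} over every unordered pair of the given
#' variants (all non-monomorphic variants by default): C(k, 2) rows,
#' sorted by the interaction p-value ascending.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @param variants character vector of variant ids (default: all
#'   non-monomorphic variants in the cohort).
#' @param adjust include covariates (default TRUE).
#' @return data.frame with columns \code{variant_1}, \code{variant_2},
#'   \code{gene_1}, \code{gene_2}, \code{pattern}, \code{interaction_or},
#'   \code{ci_low}, \code{ci_high}, \code{p_pair}, \code{bic},
#'   \code{n_used}.
#' @export
scanAllPairs <- function(cohort, variants = NULL, adjust = TRUE) {
  vi <- variantInfo(cohort)
  if (is.null(variants))
    variants <- vi$variant_id[!vi$monomorphic]
  if (length(variants) < 2) stop("need at least 2 variants")
  geneOf <- stats::setNames(as.character(vi$gene), vi$variant_id)
  pairs <- utils::combn(variants, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pr <- scanPair(cohort, pairs[1, j], pairs[2, j], adjust = adjust)
    data.frame(variant_1 = pr$variant_1, variant_2 = pr$variant_2,
               gene_1 = unname(geneOf[pr$variant_1]),
               gene_2 = unname(geneOf[pr$variant_2]),
               pattern = pr$pattern, interaction_or = pr$interaction_or,
               ci_low = pr$ci_low, ci_high = pr$ci_high,
               p_pair = pr$p_pair, bic = pr$bic_selected,
               n_used = pr$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_pair), ]
  rownames(out) <- NULL
  out
}
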