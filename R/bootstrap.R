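#' The 3pRule per-replicate significance criterion
#'
#' A pair is significant in a bootstrap replicate when the interaction
#' p-value is below \code{p_bound} (default 0.01) and below the individual
#' p-values of its component variants. Two comparison rules are supported:
#' \code{"both"} requires p_pair below both single-variant p-values (the
#' stricter reading), \code{"any"} requires it below at least one.
#'
#' @param p_pair interaction p-value, in (0, 1].
#' @param p_snp1,p_snp2 best-mode single-variant p-values.
#' @param p_bound absolute bound, default 0.01.
#' @param rule "both" (default) or "any".
#' @return logical.
#' @export
threePRule <- function(p_pair, p_snp1, p_snp2, p_bound = 0.01,
                       rule = c("both", "any")) {
  rule <- match.arg(rule)
  stopifnot(p_pair > 0, p_pair <= 1, p_snp1 > 0, p_snp2 > 0)
  if (p_pair >= p_bound) return(FALSE)
  if (rule == "both") p_pair < p_snp1 && p_pair < p_snp2
  else p_pair < p_snp1 || p_pair < p_snp2
}

#' Bootstrap internal validation of one selected pair
#'
#' Resamples individuals with replacement \code{B} times. In each
#' replicate the pair's already-selected pattern is refitted as a fixed
#' hypothesis (no per-replicate re-selection), each component variant's
#' three inheritance modes are refitted and the minimum Wald p taken, and
#' the \code{\link{threePRule}} applied. Replicates with a degenerate
#' resample (single-class outcome, constant codings, non-convergence)
#' count as non-significant and are tallied. The significance percentage
#' is 100 x (passing replicates) / B.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @param variant_1,variant_2 the pair.
#' @param pattern the selected pattern label (from \code{\link{scanPair}}).
#' @param B replicate count, default 500.
#' @param seed integer seed; the same seed reproduces the same percentage
#'   bit-exactly.
#' @param rule 3pRule comparison rule, "both" or "any".
#' @param stratified logical; resample within outcome classes instead of
#'   the plain (unstratified) bootstrap. Default FALSE.
#' @param adjust include covariates (default TRUE).
#' @return list of class \code{"validationResult"}: \code{pair},
#'   \code{pattern}, \code{B}, \code{significant_replicates},
#'   \code{significance_pct}, \code{degenerate_replicates}.
#' @export
bootstrapSignificance <- function(cohort, variant_1, variant_2, pattern,
                                  B = 500, seed = 1,
                                  rule = c("both", "any"),
                                  stratified = FALSE, adjust = TRUE) {
  rule <- match.arg(rule)
  if (B < 1) stop("B must be >= 1")
  if (is.character(pattern)) pattern <- patternByLabel(pattern)
  g1 <- .variantDosage(cohort, variant_1)
  g2 <- .variantDosage(cohort, variant_2)
  y <- phenotype(cohort)
  cv <- if (adjust) covariates(cohort) else NULL
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y)
  if (!is.null(cv)) keep <- keep & stats::complete.cases(cv)
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  if (!is.null(cv)) cv <- cv[keep, , drop = FALSE]
  n <- length(y)
  oldSeed <- .saveRngState()
  on.exit(.restoreRngState(oldSeed))
  set.seed(seed)
  nSig <- 0L; nDegen <- 0L
  for (b in seq_len(B)) {
    idx <- if (stratified) {
      c(sample(which(y == 1), sum(y == 1), replace = TRUE),
        sample(which(y == 0), sum(y == 0), replace = TRUE))
    } else sample.int(n, n, replace = TRUE)
    res <- .replicateThreeP(y[idx], g1[idx], g2[idx],
                            if (is.null(cv)) NULL
                            else cv[idx, , drop = FALSE],
                            pattern, rule)
    if (is.na(res)) nDegen <- nDegen + 1L
    else if (res) nSig <- nSig + 1L
  }
  structure(list(pair = c(variant_1, variant_2),
                 pattern = pattern$label, B = B,
                 significant_replicates = nSig,
                 significance_pct = 100 * nSig / B,
                 degenerate_replicates = nDegen),
            class = "validationResult")
}

# One bootstrap replicate: fixed-pattern p_pair + per-variant best-of-three
# p, then the 3pRule. NA = degenerate replicate (counts as non-significant).
.replicateThreeP <- function(y, g1, g2, cv, pattern, rule) {
  des <- patternDesign(pattern, g1, g2, cv)
  if (!des$fittable) return(NA)
  fit <- tryCatch(fitLogistic(y[which(des$y_keep)], des$X),
                  error = function(e) e)
  if (inherits(fit, "error") || !fit$converged ||
      is.na(fit$wald_p[[des$product_col]])) return(NA)
  p_pair <- fit$wald_p[[des$product_col]]
  pSnp <- function(g) {
    ps <- c()
    for (m in c("additive", "dominant", "recessive")) {
      x <- codeGenotype(g, m)
      if (length(unique(x)) < 2) next
      X <- cbind(`(Intercept)` = 1, snp = x)
      if (!is.null(cv)) X <- cbind(X, as.matrix(cv))
      f <- tryCatch(fitLogistic(y, X), error = function(e) NULL)
      if (!is.null(f) && f$converged && !is.na(f$wald_p[["snp"]]))
        ps <- c(ps, f$wald_p[["snp"]])
    }
    if (!length(ps)) NA_real_ else min(ps)
  }
  p1 <- pSnp(g1); p2 <- pSnp(g2)
  if (is.na(p1) || is.na(p2)) return(NA)
  threePRule(p_pair, p1, p2, rule = rule)
}

#' @export
print.validationResult <- function(x, ...) {
  cat(x$pair[1], "x", x$pair[2], "[", x$pattern, "]: ",
      sprintf("%.1f%% significant over B=%d (%d degenerate)\n",
              x$significance_pct, x$B, x$degenerate_replicates))
  invisible(x)
}

#' Final significant-pair selection
#'
#' Keeps pairs with an interaction p-value below \code{alpha} on the
#' original data and a bootstrap significance percentage strictly above
#' \code{pct_threshold}, sorted by p ascending.
#'
#' @param scan_table output of \code{\link{scanAllPairs}} (or a subset).
#' @param validation_table data.frame with columns \code{variant_1},
#'   \code{variant_2}, \code{significance_pct}
#'   (see \code{\link{validatePairs}}).
#' @param alpha final p threshold, default 0.05.
#' @param pct_threshold bootstrap percentage threshold, default 65.
#' @return the selected rows of \code{scan_table} with
#'   \code{significance_pct} appended.
#' @export
selectSignificantPairs <- function(scan_table, validation_table,
                                   alpha = 0.05, pct_threshold = 65) {
  if (!nrow(validation_table))
    return(cbind(scan_table[0, ], significance_pct = numeric(0)))
  key <- function(df) paste(df$variant_1, df$variant_2, sep = "|")
  m <- match(key(scan_table), key(validation_table))
  out <- scan_table
  out$significance_pct <- validation_table$significance_pct[m]
  out <- out[!is.na(out$significance_pct) & out$p_pair < alpha &
               out$significance_pct > pct_threshold, , drop = FALSE]
  out[order(out$p_pair), , drop = FALSE]
}

#' Bootstrap-validate a table of scanned pairs
#'
#' Convenience wrapper: runs \code{\link{bootstrapSignificance}} for each
#' row of a scan table (by default only rows with p below \code{alpha}),
#' deriving a deterministic per-pair substream from the base seed.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @param scan_table output of \code{\link{scanAllPairs}}.
#' @param B replicates, default 500.
#' @param seed base seed.
#' @param alpha only validate pairs with p_pair below this (default 0.05);
#'   use 1 to validate all rows.
#' @param rule 3pRule comparison rule.
#' @return data.frame: variant_1, variant_2, pattern, B,
#'   significant_replicates, significance_pct, degenerate_replicates.
#' @export
validatePairs <- function(cohort, scan_table, B = 500, seed = 1,
                          alpha = 0.05, rule = c("both", "any")) {
  rule <- match.arg(rule)
  todo <- scan_table[!is.na(scan_table$p_pair) &
                       scan_table$p_pair < alpha, , drop = FALSE]
  rows <- lapply(seq_len(nrow(todo)), function(i) {
    vr <- bootstrapSignificance(
      cohort, todo$variant_1[i], todo$variant_2[i], todo$pattern[i],
      B = B, seed = deriveSeed(seed, i), rule = rule)
    data.frame(variant_1 = todo$variant_1[i],
               variant_2 = todo$variant_2[i],
               pattern = vr$pattern, B = vr$B,
               significant_replicates = vr$significant_replicates,
               significance_pct = vr$significance_pct,
               degenerate_replicates = vr$degenerate_replicates,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(variant_1 = character(0), variant_2 = character(0),
                      pattern = character(0), B = integer(0),
                      significant_replicates = integer(0),
                      significance_pct = numeric(0),
                      degenerate_replicates = integer(0)))
  do.call(rbind, rows)
}
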