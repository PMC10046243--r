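#' Genotype-combination prevalence grid for a variant pair
#'
#' Cross-tabulates the two variants' genotypes (3 x 3 dosage combinations)
#' among complete cases and reports, per cell, the phenotype prevalence
#' and the cell sample size, in the layout of a two-SNP genotype grid.
#' When a pattern is supplied, an overlay marks the cells its product term
#' codes as 1 (the grouped exposure cells). Cell labels are allele pairs
#' written major-allele first.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @param variant_1,variant_2 variant ids (variant_1 indexes rows).
#' @param pattern optional pattern label or single-row pattern data.frame.
#' @return list of class \code{"prevalenceGrid"}: \code{prevalence} and
#'   \code{n} (3 x 3 matrices, dimnames = genotype labels; prevalence NA
#'   where n = 0), \code{overlay} (logical 3 x 3 or NULL),
#'   \code{overall_prevalence}, \code{n_total}.
#' @export
prevalenceGrid <- function(cohort, variant_1, variant_2, pattern = NULL) {
  g1 <- .variantDosage(cohort, variant_1)
  g2 <- .variantDosage(cohort, variant_2)
  y <- phenotype(cohort)
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y)
  if (!sum(keep)) stop("no complete cases for this pair")
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  nmat <- matrix(0L, 3, 3); pmat <- matrix(NA_real_, 3, 3)
  for (i in 0:2) for (j in 0:2) {
    cell <- g1 == i & g2 == j
    nmat[i + 1, j + 1] <- sum(cell)
    if (sum(cell)) pmat[i + 1, j + 1] <- mean(y[cell])
  }
  vi <- variantInfo(cohort)
  labs <- function(v) {
    r <- vi[vi$variant_id == v, ]
    minor <- r$minor_allele
    major <- setdiff(c(r$allele_a, r$allele_b), minor)[1]
    sep <- if (max(nchar(c(minor, major))) > 1) "/" else ""
    c(paste(major, major, sep = sep), paste(major, minor, sep = sep),
      paste(minor, minor, sep = sep))
  }
  dimnames(nmat) <- dimnames(pmat) <- list(labs(variant_1),
                                           labs(variant_2))
  overlay <- NULL
  if (!is.null(pattern)) {
    if (is.character(pattern)) pattern <- patternByLabel(pattern)
    x1 <- codeGenotype(0:2, pattern$mode1, pattern$dir1)
    x2 <- codeGenotype(0:2, pattern$mode2, pattern$dir2)
    overlay <- outer(x1, x2) != 0
    dimnames(overlay) <- dimnames(nmat)
  }
  structure(list(prevalence = pmat, n = nmat, overlay = overlay,
                 overall_prevalence = mean(y), n_total = length(y)),
            class = "prevalenceGrid")
}

#' @export
print.prevalenceGrid <- function(x, ...) {
  disp <- matrix("", 3, 3, dimnames = dimnames(x$n))
  for (i in 1:3) for (j in 1:3) {
    disp[i, j] <- if (x$n[i, j] == 0) "- (0)" else
      sprintf("%.2f (%d)%s", x$prevalence[i, j], x$n[i, j],
              if (!is.null(x$overlay) && x$overlay[i, j]) " *" else "")
  }
  cat(sprintf("Prevalence grid, overall %.2f (n=%d)%s\n",
              x$overall_prevalence, x$n_total,
              if (is.null(x$overlay)) "" else "; * = pattern cells"))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Descriptive cohort summary with optional two-group comparison
#'
#' Age mean/SD, study-site split, ancestry mean/SD and phenotype
#' prevalence. When a second cohort is given, group differences are
#' tested with a t-test for age and chi-square tests for site and
#' outcome.
#'
#' @param cohort a \linkS4class{SnpCohort}.
#' @param cohort2 optional second \linkS4class{SnpCohort} to compare.
#' @return list: \code{n}, \code{age_mean}, \code{age_sd},
#'   \code{site_louisiana_n}, \code{site_louisiana_pct},
#'   \code{ancestry_mean}, \code{ancestry_sd}, \code{cases_n},
#'   \code{prevalence_pct} (1 decimal, as conventionally rendered);
#'   when comparing, also \code{p_age}, \code{p_site}, \code{p_outcome}.
#' @export
cohortSummary <- function(cohort, cohort2 = NULL) {
  one <- function(ch) {
    cv <- covariates(ch); y <- phenotype(ch)
    list(stratum = stratumLabel(ch), n = length(y),
         age_mean = mean(cv$age), age_sd = stats::sd(cv$age),
         site_louisiana_n = sum(cv$site == 1),
         site_louisiana_pct = round(100 * mean(cv$site == 1), 1),
         ancestry_mean = mean(cv$ancestry),
         ancestry_sd = stats::sd(cv$ancestry),
         cases_n = sum(y == 1, na.rm = TRUE),
         prevalence_pct = round(100 * mean(y, na.rm = TRUE), 1))
  }
  out <- one(cohort)
  if (!is.null(cohort2)) {
    s2 <- one(cohort2)
    a1 <- covariates(cohort)$age; a2 <- covariates(cohort2)$age
    out$comparison <- s2
    out$p_age <- stats::t.test(a1, a2)$p.value
    siteTab <- rbind(c(out$site_louisiana_n,
                       out$n - out$site_louisiana_n),
                     c(s2$site_louisiana_n, s2$n - s2$site_louisiana_n))
    out$p_site <- .safeChisqP(siteTab)
    outTab <- rbind(c(out$cases_n, out$n - out$cases_n),
                    c(s2$cases_n, s2$n - s2$cases_n))
    out$p_outcome <- .safeChisqP(outTab)
  }
  out
}

.safeChisqP <- function(tab) {
  if (any(colSums(tab) == 0) ||
      identical(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ])))
    return(1)
  unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$p.value)
}

#' Render a pair-scan table at publication precision
#'
#' Formats odds ratios and CIs to two decimals and p-values to three, in
#' the familiar pair-table layout (SNP pair, genes, pattern, OR (95\% CI),
#' p, and bootstrap significance \% when present).
#'
#' @param scan_table output of \code{\link{scanAllPairs}}, optionally with
#'   a \code{significance_pct} column.
#' @return data.frame of display strings.
#' @export
renderPairTable <- function(scan_table) {
  out <- data.frame(
    `SNP Pair` = paste(scan_table$variant_1, scan_table$variant_2,
                       sep = "_"),
    Gene1 = scan_table$gene_1, Gene2 = scan_table$gene_2,
    Pattern = scan_table$pattern,
    `OR (95% CI)` = sprintf("%.2f (%.2f, %.2f)",
                            scan_table$interaction_or,
                            scan_table$ci_low, scan_table$ci_high),
    `p-Value` = sprintf("%.3f", scan_table$p_pair),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(scan_table$significance_pct))
    out$`Significance%` <- sprintf("%.1f", scan_table$significance_pct)
  out
}

# stable TSV writer used by the pipeline: tab separated, no quoting,
# fixed column order as supplied
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full association pipeline
#'
#' Drives the whole analysis: obtain the cohort (simulate a profile
#' stratum, or read a genotype table), assign minor alleles, run the
#' single-variant scan, the all-pairs 45-pattern interaction scan, the
#' bootstrap validation of the pairs below \code{alpha}, and the final
#' selection; writes all tables as TSV plus a JSON run manifest (seeds,
#' thresholds, package version) for reproducibility. Reruns with the same
#' configuration produce byte-identical outputs.
#'
#' @param config list with elements: either \code{stratum} ("EA"/"AA" or a
#'   profile path) with optional \code{effect}/\code{effect_pair}/\code{n},
#'   or \code{genotype_table} + \code{variants} (see
#'   \code{\link{readGenotypeTable}}); \code{seed} (default 1); \code{B}
#'   (default 500); \code{alpha} (default 0.05); \code{pct_threshold}
#'   (default 65); \code{rule} (default "both"); \code{out_dir} (required).
#' @return invisibly, a list with \code{cohort}, \code{summary},
#'   \code{single_snp}, \code{pairs}, \code{validation}, \code{selected},
#'   \code{manifest}, \code{files}.
#' @export
runPipeline <- function(config) {
  need <- c("out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config lacks required field(s): ", paste(miss, collapse = ", "))
  if (is.null(config$stratum) && is.null(config$genotype_table))
    stop("config must supply either 'stratum' or 'genotype_table'")
  if (!is.null(config$genotype_table) && is.null(config$variants))
    stop("config with 'genotype_table' must also supply 'variants'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  B <- if (is.null(config$B)) 500L else as.integer(config$B)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  pct <- if (is.null(config$pct_threshold)) 65 else config$pct_threshold
  rule <- if (is.null(config$rule)) "both" else config$rule
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)

  cohort <- if (!is.null(config$genotype_table)) {
    readGenotypeTable(config$genotype_table, config$variants,
                      stratum = if (is.null(config$stratum_label))
                        "unknown" else config$stratum_label)
  } else {
    simulateStudyCohort(config$stratum, effect = config$effect,
                        effect_pair = config$effect_pair,
                        n = config$n, seed = seed)
  }
  cohort <- determineMinorAlleles(cohort)
  summ <- cohortSummary(cohort)
  snpTab <- singleSnpScan(cohort)
  pairTab <- scanAllPairs(cohort)
  valTab <- validatePairs(cohort, pairTab, B = B,
                          seed = deriveSeed(seed, 77), alpha = alpha,
                          rule = rule)
  selTab <- selectSignificantPairs(pairTab, valTab, alpha = alpha,
                                   pct_threshold = pct)
  files <- c(
    single_snp = .writeTsv(snpTab, outfile("single_snp.tsv")),
    pairs = .writeTsv(pairTab, outfile("pairs.tsv")),
    validation = .writeTsv(valTab, outfile("validated.tsv")),
    selected = .writeTsv(selTab, outfile("selected.tsv")))
  manifest <- list(
    package = "sipiScan",
    version = as.character(utils::packageVersion("sipiScan")),
    seed = seed, B = B, alpha = alpha, pct_threshold = pct, rule = rule,
    stratum = stratumLabel(cohort), n = ncol(cohort),
    n_variants = nrow(cohort),
    bonferroni_single = as.numeric(bonferroniThreshold(nrow(cohort))),
    bonferroni_pairs = as.numeric(
      bonferroniThreshold(choose(nrow(cohort), 2))))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, manifest = outfile("manifest.json"))
  invisible(list(cohort = cohort, summary = summ, single_snp = snpTab,
                 pairs = pairTab, validation = valTab, selected = selTab,
                 manifest = manifest, files = files))
}
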