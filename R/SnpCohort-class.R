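#' SnpCohort: genotype dosages, phenotype and covariates for one stratum
#'
#' An S4 container for a single case-control stratum, extending
#' \linkS4class{SummarizedExperiment}. Rows are biallelic polymorphisms
#' (SNPs or small indels treated as alleles, e.g. the DHFR 19-bp del/ins),
#' columns are samples. The single assay, \code{"dosage"}, holds
#' minor-allele dosages in \{0, 1, 2\} with \code{NA} for missing calls.
#' \code{rowData} carries the per-variant metadata (alleles, minor-allele
#' assignment, MAF); \code{colData} carries the binary phenotype
#' (1 = high-aggressive disease, 0 = low-aggressive) and the adjustment
#' covariates: age in years, study-site indicator (1 = Louisiana,
#' 0 = North Carolina) and the genetic-ancestry proportion in [0, 1].
#'
#' Minor-allele assignment is cohort-specific: the same allele can be minor
#' in one stratum and major in another, so dosages are only comparable
#' within a stratum after \code{\link{determineMinorAlleles}}.
#'
#' @slot stratumLabel character(1), e.g. "EA" or "AA".
#' @seealso \code{\link{determineMinorAlleles}}, \code{\link{scanAllPairs}}
#' @export
setClass("SnpCohort",
  contains = "SummarizedExperiment",
  representation(stratumLabel = "character"),
  prototype(stratumLabel = "unknown")
)

.validSnpCohort <- function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("phenotype", "age", "site", "ancestry")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("phenotype" %in% colnames(cd)) {
    ph <- cd$phenotype
    if (!all(ph[!is.na(ph)] %in% c(0, 1)))
      msg <- c(msg, "phenotype must be binary 0/1 (NA allowed)")
  }
  if ("ancestry" %in% colnames(cd)) {
    an <- cd$ancestry
    if (any(an[!is.na(an)] < 0 | an[!is.na(an)] > 1))
      msg <- c(msg, "ancestry proportions must lie in [0, 1]")
  }
  rd <- SummarizedExperiment::rowData(object)
  needr <- c("variant_id", "allele_a", "allele_b", "minor_allele")
  missr <- setdiff(needr, colnames(rd))
  if (length(missr))
    msg <- c(msg, paste0("rowData lacks: ", paste(missr, collapse = ", ")))
  if (!length(msg)) {
    ok <- rd$minor_allele == rd$allele_a | rd$minor_allele == rd$allele_b
    if (!all(ok))
      msg <- c(msg, "minor_allele must be one of allele_a/allele_b")
  }
  if (length(object@stratumLabel) != 1L)
    msg <- c(msg, "stratumLabel must be a single string")
  if (is.null(msg)) TRUE else msg
}
setValidity("SnpCohort", .validSnpCohort)

#' Construct a SnpCohort
#'
#' @param dosage integer matrix, variants x samples, minor-allele dosages in
#'   \{0,1,2\} with NA for missing.
#' @param variants data.frame of variant metadata with columns
#'   \code{variant_id}, \code{chromosome}, \code{position}, \code{gene},
#'   \code{allele_a}, \code{allele_b}, \code{minor_allele}; optional
#'   \code{maf}, \code{monomorphic}.
#' @param phenotype binary 0/1 vector, one per sample (1 = high aggressive).
#' @param age numeric vector, years.
#' @param site binary 0/1 vector (1 = Louisiana).
#' @param ancestry numeric vector of ancestry proportions in [0, 1].
#' @param stratum character(1) stratum label, e.g. "EA".
#' @param sampleIds optional character vector of sample identifiers.
#' @return A \linkS4class{SnpCohort}.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L), nrow = 1,
#'             dimnames = list("rs1", NULL))
#' v <- data.frame(variant_id = "rs1", chromosome = "1", position = 100,
#'                 gene = "G1", allele_a = "A", allele_b = "G",
#'                 minor_allele = "A")
#' SnpCohort(d, v, phenotype = c(0, 1, 0, 1), age = c(60, 65, 70, 62),
#'           site = c(1, 0, 1, 0), ancestry = c(0.9, 0.95, 0.99, 0.97))
#' @export
SnpCohort <- function(dosage, variants, phenotype, age, site, ancestry,
                      stratum = "unknown", sampleIds = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sampleIds))
    sampleIds <- colnames(dosage)
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%04d", seq_len(ncol(dosage)))
  colnames(dosage) <- sampleIds
  if (is.null(rownames(dosage)))
    rownames(dosage) <- variants$variant_id
  if (is.null(variants$maf))
    variants$maf <- NA_real_
  if (is.null(variants$monomorphic))
    variants$monomorphic <- FALSE
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(variants, row.names = variants$variant_id),
    colData = S4Vectors::DataFrame(
      phenotype = as.numeric(phenotype),
      age = as.numeric(age),
      site = as.numeric(site),
      ancestry = as.numeric(ancestry),
      row.names = sampleIds
    )
  )
  methods::new("SnpCohort", se, stratumLabel = as.character(stratum))
}

#' @describeIn SnpCohort the variants x samples dosage matrix.
#' @param x,object a SnpCohort.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setMethod("dosages", "SnpCohort", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @describeIn SnpCohort the binary phenotype vector.
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @export
setMethod("phenotype", "SnpCohort", function(x)
  SummarizedExperiment::colData(x)$phenotype)

#' @describeIn SnpCohort data.frame of adjustment covariates
#'   (age, site, ancestry).
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @export
setMethod("covariates", "SnpCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(age = cd$age, site = cd$site, ancestry = cd$ancestry,
             row.names = rownames(cd))
})

#' @describeIn SnpCohort data.frame of per-variant metadata.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @export
setMethod("variantInfo", "SnpCohort", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @describeIn SnpCohort the stratum label.
#' @export
setGeneric("stratumLabel", function(x) standardGeneric("stratumLabel"))

#' @export
setMethod("stratumLabel", "SnpCohort", function(x) x@stratumLabel)

#' @export
setMethod("show", "SnpCohort", function(object) {
  d <- dosages(object)
  ph <- phenotype(object)
  cat("SnpCohort (stratum ", object@stratumLabel, "): ",
      nrow(d), " variants x ", ncol(d), " samples\n", sep = "")
  cat("  high-aggressive: ", sum(ph == 1, na.rm = TRUE), "/",
      sum(!is.na(ph)),
      sprintf(" (%.1f%%)", 100 * mean(ph, na.rm = TRUE)), "\n", sep = "")
  cat("  missing genotype calls: ", sum(is.na(d)), "\n", sep = "")
  cat("  variants: ",
      paste(utils::head(rownames(d), 5), collapse = ", "),
      if (nrow(d) > 5) ", ..." else "", "\n", sep = "")
})

# internal: dosage vector for one variant id (samples along the vector)
.variantDosage <- function(cohort, variant_id) {
  d <- dosages(cohort)
  if (!variant_id %in% rownames(d))
    stop("unknown variant: ", variant_id)
  as.numeric(d[variant_id, ])
}
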