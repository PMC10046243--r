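#' Read a delimited sample-by-variant genotype table
#'
#' Reads a header-ed delimited file with one row per sample and columns for
#' the binary phenotype, the covariates (age, site, ancestry) and one
#' column per variant. Genotype cells may be dosages (0/1/2) or allele
#' pairs such as \code{"A/G"}; allele pairs are counted against the
#' variant's declared minor allele. Unparseable cells and the configured
#' missing code become \code{NA}.
#'
#' @param path file path.
#' @param variants variant metadata data.frame (see \code{\link{SnpCohort}});
#'   the table must contain one column per \code{variant_id}.
#' @param sep field separator, default tab.
#' @param missing_code string treated as missing, default \code{"NA"}.
#' @param phenotype_col,age_col,site_col,ancestry_col column names.
#' @param stratum stratum label attached to the cohort.
#' @return a \linkS4class{SnpCohort}.
#' @export
readGenotypeTable <- function(path, variants, sep = "\t",
                              missing_code = "NA",
                              phenotype_col = "phenotype",
                              age_col = "age", site_col = "site",
                              ancestry_col = "ancestry",
                              stratum = "unknown") {
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           na.strings = missing_code,
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(phenotype_col, age_col, site_col, ancestry_col,
            variants$variant_id)
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("genotype table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  ph <- suppressWarnings(as.numeric(tab[[phenotype_col]]))
  if (!all(ph[!is.na(ph)] %in% c(0, 1)))
    stop("phenotype column must be binary 0/1")
  n <- nrow(tab)
  dosage <- matrix(NA_integer_, nrow = nrow(variants), ncol = n,
                   dimnames = list(variants$variant_id, NULL))
  for (i in seq_len(nrow(variants))) {
    dosage[i, ] <- .parseGenotypeCells(tab[[variants$variant_id[i]]],
                                       variants$minor_allele[i],
                                       variants$allele_a[i],
                                       variants$allele_b[i])
  }
  sampleIds <- if ("sample_id" %in% colnames(tab)) tab$sample_id else NULL
  SnpCohort(dosage, variants, phenotype = ph,
            age = as.numeric(tab[[age_col]]),
            site = as.numeric(tab[[site_col]]),
            ancestry = as.numeric(tab[[ancestry_col]]),
            stratum = stratum, sampleIds = sampleIds)
}

# Parse a character vector of genotype cells (dosage or "X/Y" allele pairs)
# into minor-allele dosages; anything unparseable becomes NA.
.parseGenotypeCells <- function(cells, minor, allele_a, allele_b) {
  out <- rep(NA_integer_, length(cells))
  cells <- trimws(cells)
  isDos <- !is.na(cells) & cells %in% c("0", "1", "2")
  out[isDos] <- as.integer(cells[isDos])
  pair <- !is.na(cells) & !isDos & grepl("/", cells, fixed = TRUE)
  if (any(pair)) {
    parts <- strsplit(cells[pair], "/", fixed = TRUE)
    valid <- c(allele_a, allele_b)
    out[pair] <- vapply(parts, function(p) {
      if (length(p) != 2 || !all(p %in% valid)) return(NA_integer_)
      sum(p == minor)
    }, integer(1))
  }
  out
}

#' Read biallelic genotypes from a VCF file
#'
#' Thin wrapper over \code{VariantAnnotation::readVcf} that extracts GT
#' calls as ALT-allele dosages. Multi-allelic records are skipped with a
#' warning; half-missing calls (e.g. \code{"./1"}) are treated as missing.
#' The returned dosages count the ALT allele; run
#' \code{\link{determineMinorAlleles}} on the assembled cohort to
#' re-orient to the cohort minor allele.
#'
#' @param path VCF file path (VCF 4.x, GT format field required).
#' @param sample_subset optional character vector of sample names to keep.
#' @return list with \code{dosage} (variants x samples integer matrix of
#'   ALT dosages) and \code{variants} (data.frame: variant_id, chromosome,
#'   position, ref, alt).
#' @export
readVcfBiallelic <- function(path, sample_subset = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!"GT" %in% rownames(VariantAnnotation::geno(
        VariantAnnotation::header(vcf))))
    stop("VCF has no GT format field")
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  if (any(nalt != 1)) {
    warning(sum(nalt != 1), " multi-allelic record(s) skipped")
    vcf <- vcf[nalt == 1]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, colnames(gt))
    if (length(miss)) stop("samples not in VCF: ",
                           paste(miss, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  hit <- clean %in% names(known)
  dos[hit] <- known[clean[hit]]
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    variant_id = rownames(gt),
    chromosome = as.character(GenomeInfoDb::seqnames(rr)),
    position = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                 `[`, character(1), 1L),
    stringsAsFactors = FALSE)
  list(dosage = dos, variants = variants)
}
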