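#' Code a genotype dosage under an inheritance mode and risk direction
#'
#' Maps minor-allele dosages in \{0,1,2\} to a model predictor. Base
#' (original-direction) codings: additive = dosage; dominant = minor-allele
#' carrier indicator (dosage >= 1); recessive = minor-homozygote indicator
#' (dosage == 2). The reverse direction re-expresses the coding in terms of
#' the major allele: \code{2 - g} for additive and the complement
#' \code{1 - base} for dominant/recessive.
#'
#' @param g dosage vector in \{0,1,2\} (NA passed through).
#' @param mode "additive", "dominant" or "recessive" (or "A"/"D"/"R").
#' @param direction "original" or "reverse".
#' @return numeric coded vector.
#' @export
codeGenotype <- function(g, mode, direction = "original") {
  mode <- .normMode(mode)
  direction <- match.arg(direction, c("original", "reverse"))
  base <- switch(mode,
    additive  = as.numeric(g),
    dominant  = as.numeric(g >= 1),
    recessive = as.numeric(g == 2))
  if (direction == "original") return(base)
  if (mode == "additive") 2 - base else 1 - base
}

.normMode <- function(mode) {
  full <- c(A = "additive", D = "dominant", R = "recessive")
  if (mode %in% names(full)) return(unname(full[mode]))
  match.arg(mode, unname(full))
}

#' Enumerate the 45-pattern interaction catalogue
#'
#' For each of the five inheritance-mode combinations (AA, DD, DR, RD, RR;
#' first letter = first SNP's mode, A = additive, D = dominant,
#' R = recessive) there are nine models crossing the model structure with
#' the risk direction: the hierarchical full model (both main effects plus
#' the interaction; original directions only, since direction reversal
#' leaves the full model's fit unchanged), one-main-effect models
#' \code{M1_int}/\code{M2_int} with the retained SNP coded in either
#' direction, and interaction-only models with all four direction
#' combinations. 5 x (1 + 2 + 2 + 4) = 45 patterns.
#'
#' @return data.frame with one row per pattern: \code{label},
#'   \code{mode1}, \code{mode2} ("A"/"D"/"R"), \code{structure}
#'   ("Full", "M1_int", "M2_int", "int_only"), \code{dir1}, \code{dir2}
#'   ("original"/"reverse"), in canonical order.
#' @export
interactionPatterns <- function() {
  combos <- c("AA", "DD", "DR", "RD", "RR")
  rows <- lapply(combos, function(cmb) {
    m1 <- substr(cmb, 1, 1); m2 <- substr(cmb, 2, 2)
    d <- function(ch) if (ch == "o") "original" else "reverse"
    spec <- list(
      c("Full",     "o", "o", "Full"),
      c("M1_int",   "o", "o", "M1_int_o1"),
      c("M1_int",   "r", "o", "M1_int_r1"),
      c("M2_int",   "o", "o", "M2_int_o2"),
      c("M2_int",   "o", "r", "M2_int_r2"),
      c("int_only", "o", "o", "int_oo"),
      c("int_only", "o", "r", "int_or"),
      c("int_only", "r", "o", "int_ro"),
      c("int_only", "r", "r", "int_rr"))
    do.call(rbind, lapply(spec, function(s)
      data.frame(label = paste0(cmb, "_", s[4]),
                 mode1 = m1, mode2 = m2, structure = s[1],
                 dir1 = d(s[2]), dir2 = d(s[3]),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$label
  out
}

#' Look up one pattern by label
#'
#' @param label canonical pattern label, e.g. "DR_int_or".
#' @return single-row data.frame as in \code{\link{interactionPatterns}}.
#' @export
patternByLabel <- function(label) {
  cat45 <- interactionPatterns()
  if (!label %in% cat45$label) stop("unknown pattern label: ", label)
  cat45[label, , drop = FALSE]
}

#' Build the design matrix for one interaction pattern
#'
#' Applies the pattern's mode/direction coding to each variant (the
#' reversed coding, where present, affects every term containing that
#' variant: its main effect and the product) and assembles the logistic
#' design: intercept, the structure's main-effect columns, the product
#' term, and the adjustment covariates. Complete cases only.
#'
#' @param pattern single-row pattern data.frame
#'   (see \code{\link{interactionPatterns}}) or a label string.
#' @param g1,g2 dosage vectors.
#' @param covariateData data.frame of covariates (or NULL for none).
#' @return list: \code{X} design matrix (with intercept),
#'   \code{y_keep} logical complete-case index into the input vectors,
#'   \code{product_col} name of the product-term column,
#'   \code{fittable} FALSE when the product term (or a main-effect term)
#'   is constant on the complete cases, with \code{reason}.
#' @export
patternDesign <- function(pattern, g1, g2, covariateData = NULL) {
  if (is.character(pattern)) pattern <- patternByLabel(pattern)
  keep <- !is.na(g1) & !is.na(g2)
  if (!is.null(covariateData))
    keep <- keep & stats::complete.cases(covariateData)
  x1 <- codeGenotype(g1[keep], pattern$mode1, pattern$dir1)
  x2 <- codeGenotype(g2[keep], pattern$mode2, pattern$dir2)
  prod <- x1 * x2
  cols <- switch(pattern$structure,
    Full     = list(x1 = x1, x2 = x2, x1x2 = prod),
    M1_int   = list(x1 = x1, x1x2 = prod),
    M2_int   = list(x2 = x2, x1x2 = prod),
    int_only = list(x1x2 = prod))
  X <- cbind(`(Intercept)` = rep(1, sum(keep)),
             do.call(cbind, cols))
  if (!is.null(covariateData)) {
    cv <- as.matrix(covariateData[keep, , drop = FALSE])
    X <- cbind(X, cv)
  }
  fittable <- TRUE; reason <- NA_character_
  snpCols <- names(cols)
  for (nm in snpCols) {
    if (length(unique(cols[[nm]])) < 2) {
      fittable <- FALSE
      reason <- paste0("constant term: ", nm)
      break
    }
  }
  list(X = X, y_keep = keep, product_col = "x1x2",
       fittable = fittable, reason = reason)
}
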