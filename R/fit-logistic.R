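#' Maximum-likelihood logistic regression on an explicit design matrix
#'
#' Wrapper over \code{stats::glm.fit} (binomial, logit link) with a tight
#' convergence tolerance and explicit degeneracy handling: a single-class
#' outcome or a constant non-intercept predictor raises an error instead of
#' producing spurious estimates, and suspected separation (non-convergence
#' or runaway coefficients) is flagged via \code{converged = FALSE}.
#' Standard errors come from the inverse observed information; per-term
#' p-values are two-sided Wald tests.
#'
#' @param y binary 0/1 response vector (no NAs).
#' @param X numeric design matrix including an intercept column; rows
#'   correspond to \code{y}.
#' @return list of class \code{"logisticFit"}: \code{coefficients},
#'   \code{se}, \code{wald_p} (named per column; NA for aliased columns),
#'   \code{log_likelihood}, \code{n_used}, \code{k} (estimated
#'   coefficients = rank), \code{converged}, \code{aliased}.
#' @export
fitLogistic <- function(y, X) {
  if (any(is.na(y)) || any(is.na(X)))
    stop("fitLogistic requires complete cases")
  if (length(unique(y)) < 2)
    stop("degenerate outcome: response has a single class")
  constCol <- apply(X, 2, function(col) all(col == col[1]))
  # exactly one constant column is tolerated: the all-ones intercept
  nConst <- sum(constCol)
  if (nConst > 1 || (nConst == 1 && X[1, which(constCol)] != 1))
    stop("degenerate predictor: constant non-intercept column(s): ",
         paste(colnames(X)[constCol], collapse = ", "))
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  rank <- fit$rank
  # unscaled covariance of the estimated (non-aliased) coefficients,
  # recovered from the pivoted QR exactly as summary.glm does
  p1 <- seq_len(rank)
  Qr <- fit$qr
  covUn <- chol2inv(Qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, length(coefs))
  names(se) <- names(coefs)
  se[Qr$pivot[p1]] <- sqrt(diag(covUn))
  z <- coefs / se
  wald_p <- 2 * stats::pnorm(-abs(z))
  mu <- fit$fitted.values
  logLik <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  bigCoef <- any(abs(coefs[!aliased]) > 15)
  structure(list(
    coefficients = coefs, se = se, wald_p = wald_p,
    log_likelihood = logLik, n_used = length(y), k = rank,
    converged = fit$converged && !bigCoef, aliased = aliased),
    class = "logisticFit")
}

#' Odds ratio and 95\% CI for one fitted term
#'
#' @param fit a \code{"logisticFit"}.
#' @param term coefficient name.
#' @return named numeric: \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{p}.
#' @export
termOddsRatio <- function(fit, term) {
  b <- fit$coefficients[[term]]
  s <- fit$se[[term]]
  c(or = exp(b), ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
    p = fit$wald_p[[term]])
}

#' Bayesian information criterion of a logistic fit
#'
#' BIC = -2 log L + k log(n), with k the number of estimated coefficients
#' (including the intercept) and n the complete-case count used in the fit.
#'
#' @param fit a \code{"logisticFit"}.
#' @return numeric BIC.
#' @export
bicOf <- function(fit) {
  -2 * fit$log_likelihood + fit$k * log(fit$n_used)
}

#' @export
print.logisticFit <- function(x, ...) {
  cat("Logistic fit: n =", x$n_used, ", k =", x$k,
      ", logLik =", format(x$log_likelihood, digits = 6),
      if (!x$converged) "(NOT converged)" else "", "\n")
  tab <- data.frame(beta = x$coefficients, se = x$se, p = x$wald_p)
  print(tab, digits = 4)
  invisible(x)
}
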