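# Independent oracles used to cross-check the package's fitting and
# selection paths. Deliberately avoid glm.fit: hand-written IRLS with
# base linear algebra, converged to machine precision.

oracle_logistic <- function(y, X, maxit = 100, tol = 1e-13) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    bnew <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    done <- max(abs(bnew - b)) < tol
    b <- bnew
    if (done) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  vc <- solve(crossprod(X, (mu * (1 - mu)) * X))
  list(coef = unname(b), se = unname(sqrt(diag(vc))), logLik = ll,
       k = ncol(X), n = length(y),
       bic = -2 * ll + ncol(X) * log(length(y)))
}

# Pearson chi-square on a 2 x c contingency table, from first principles
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# independent genotype coding: written as an explicit lookup over the
# nine (mode, direction) x dosage combinations
oracle_code <- function(g, mode, dir) {
  map <- list(
    A_o = c(0, 1, 2), A_r = c(2, 1, 0),
    D_o = c(0, 1, 1), D_r = c(1, 0, 0),
    R_o = c(0, 0, 1), R_r = c(1, 1, 0))
  key <- paste0(toupper(substr(mode, 1, 1)), "_", substr(dir, 1, 1))
  map[[key]][g + 1]
}

# exhaustive 45-pattern refit + min-BIC selection, independent of the
# package's patternDesign/scanPair path (same 1e-7 tie tolerance, fewer
# parameters then catalogue order)
oracle_select <- function(y, g1, g2, cv = NULL) {
  cat45 <- sipiScan::interactionPatterns()
  bics <- rep(NA_real_, nrow(cat45))
  ks <- bics
  for (i in seq_len(nrow(cat45))) {
    p <- cat45[i, ]
    x1 <- oracle_code(g1, p$mode1, p$dir1)
    x2 <- oracle_code(g2, p$mode2, p$dir2)
    cols <- switch(p$structure,
      Full = cbind(x1 = x1, x2 = x2, x1x2 = x1 * x2),
      M1_int = cbind(x1 = x1, x1x2 = x1 * x2),
      M2_int = cbind(x2 = x2, x1x2 = x1 * x2),
      int_only = cbind(x1x2 = x1 * x2))
    if (any(apply(cols, 2, function(cc) length(unique(cc)) < 2))) next
    X <- cbind(1, cols)
    if (!is.null(cv)) X <- cbind(X, as.matrix(cv))
    if (qr(X)$rank < ncol(X)) next
    fit <- tryCatch(oracle_logistic(y, X), error = function(e) NULL)
    if (is.null(fit) || any(abs(fit$coef) > 15)) next
    bics[i] <- fit$bic
    ks[i] <- fit$k
  }
  if (all(is.na(bics))) return(NULL)
  minB <- min(bics, na.rm = TRUE)
  cand <- which(!is.na(bics) & bics <= minB + 1e-7)
  cand <- cand[order(ks[cand], cand)]
  list(label = cat45$label[cand[1]], bic = bics[cand[1]], bics = bics)
}
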