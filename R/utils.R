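# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Smallest two-sided P reported; underflow below this is floored and flagged.
.P_FLOOR <- 1e-300

.p_from_t <- function(tval, df) {
  pmax(2 * stats::pt(-abs(tval), df), .P_FLOOR)
}

.p_from_z <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .P_FLOOR)
}

# Design matrix with intercept; covariates may be NULL, a vector, matrix or
# data.frame. Factors are not expanded here — callers pass numeric codes.
.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  .assert(nrow(X) == n, "covariate rows do not match response length")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cbind("(Intercept)" = 1, X)
}

# Error naming the offending column when the design is rank deficient.
.check_full_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(qd)
}

# OLS with t-based two-sided P. Used by phenotype prep, the MR regressions
# and the pleiotropy check; the association scan has its own vectorised path.
.ols_fit <- function(y, X) {
  .assert(is.numeric(y) && !anyNA(y), "response must be numeric without NA")
  .assert(length(y) > ncol(X), "more coefficients than observations")
  .check_full_rank(X)
  XtX <- crossprod(X)
  coef <- drop(solve(XtX, crossprod(X, y)))
  res <- drop(y - X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- coef / se
  list(coef = coef, se = se, t = tval, p = .p_from_t(tval, df),
       df = df, residuals = res, sigma2 = sigma2)
}
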