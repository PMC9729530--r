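#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA-IR = fasting insulin (uU/L) x fasting glucose (mmol/L) / 22.5.
#'
#' @param fasting_insulin Fasting insulin, uU/L (> 0). Vectorized.
#' @param fasting_glucose Fasting plasma glucose, mmol/L (> 0). Vectorized.
#' @return HOMA-IR values.
#' @export
#' @examples
#' compute_homa_ir(22.5, 1.0) # 1
compute_homa_ir <- function(fasting_insulin, fasting_glucose) {
  .assert(all(fasting_insulin > 0, na.rm = TRUE),
          "fasting insulin must be positive")
  .assert(all(fasting_glucose > 0, na.rm = TRUE),
          "fasting glucose must be positive")
  fasting_insulin * fasting_glucose / 22.5
}

#' Body mass index
#'
#' @param weight_kg Body weight in kilograms (> 0). Vectorized.
#' @param height_m Height in meters (> 0). Vectorized.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(81, 1.8) # 25
compute_bmi <- function(weight_kg, height_m) {
  .assert(all(weight_kg > 0, na.rm = TRUE), "weight must be positive")
  .assert(all(height_m > 0, na.rm = TRUE), "height must be positive")
  weight_kg / height_m^2
}

#' Covariate-adjust a trait by OLS residualization
#'
#' Regresses the trait on an intercept plus the supplied covariates and
#' returns the residuals, which are exactly orthogonal to every covariate
#' column.
#'
#' @param values Numeric trait vector.
#' @param covariates Optional vector/matrix/data.frame of covariates, rows
#'   aligned with `values`. `NULL` adjusts for the intercept only
#'   (mean-centering).
#' @return Numeric residual vector.
#' @export
#' @examples
#' residualize(c(1, 2, 4), NULL) # mean-centered
residualize <- function(values, covariates = NULL) {
  .assert(is.numeric(values) && !anyNA(values),
          "values must be numeric without NA")
  X <- .design_matrix(covariates, length(values))
  .check_full_rank(X)
  drop(values - X %*% solve(crossprod(X), crossprod(X, values)))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their ranks:
#' `qnorm((rank - 0.5) / n)` by default (the GenABEL-style offset), with
#' ties given the average rank and hence a shared quantile. The Blom offset
#' `qnorm((rank - 3/8) / (n + 1/4))` is available.
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @param offset `"half"` (default) or `"blom"`.
#' @return Numeric vector of transformed values (attributes record the
#'   offset and whether ties were present); strictly monotone in the ranks.
#' @export
#' @examples
#' inverse_normal_transform(c(1, 2, 5)) # qnorm(c(1, 3, 5) / 6)
inverse_normal_transform <- function(values, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  .assert(is.numeric(values) && !anyNA(values),
          "values must be numeric without NA")
  n <- length(values)
  .assert(n >= 2, "need at least two observations")
  .assert(stats::sd(values) > 0,
          "inverse normal transform undefined for a constant vector")
  r <- rank(values, ties.method = "average")
  q <- switch(offset,
              half = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 1 / 4))
  out <- stats::qnorm(q)
  attr(out, "offset") <- offset
  attr(out, "ties") <- anyDuplicated(values) > 0
  out
}

#' Prepare a trait for association analysis
#'
#' Applies the configured pre-transform (none, natural log, or log10),
#' residualizes on the covariates, and — for `transform = "int"` — maps the
#' residuals through the rank-based inverse normal transformation. This is
#' the standard preparation of the metabolite before the association scan,
#' which then regresses the prepared trait on dosage alone.
#'
#' @param values Numeric trait vector.
#' @param covariates Optional covariates (see [residualize()]).
#' @param transform One of `"int"` (residualize then inverse-normal,
#'   default), `"ln"`, `"log"` (log then residualize), or `"none"`
#'   (residualize only).
#' @param offset Rank offset passed to [inverse_normal_transform()].
#' @return Prepared numeric vector; attribute `"prep"` records the choices.
#' @export
prepare_trait <- function(values, covariates = NULL,
                          transform = c("int", "ln", "log", "none"),
                          offset = "half") {
  transform <- match.arg(transform)
  if (transform %in% c("ln", "log")) {
    .assert(all(values > 0), "log transform requires positive values")
    values <- if (transform == "ln") log(values) else log10(values)
  }
  res <- residualize(values, covariates)
  out <- if (transform == "int") {
    inverse_normal_transform(res, offset = offset)
  } else {
    res
  }
  attr(out, "prep") <- list(
    transform = transform,
    covariates = colnames(.design_matrix(covariates, length(values)))[-1]
  )
  out
}
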