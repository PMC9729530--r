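#' Orient instrument weights to the exposure-raising allele
#'
#' Flips any weight with a negative effect (swapping effect/other allele,
#' negating beta, complementing eaf if present) so every weight is positive
#' on its exposure-raising allele and "number of risk alleles" is
#' well-defined. Causal estimates are invariant to this relabelling.
#'
#' @param weights Data.frame with columns `SNP`, `EA`, `OA`, `BETA`
#'   (optionally `EAF`).
#' @return Re-oriented weights with all `BETA > 0`.
#' @export
orient_weights <- function(weights) {
  .assert(all(c("SNP", "EA", "OA", "BETA") %in% names(weights)),
          "weights need columns SNP, EA, OA, BETA")
  .assert(all(is.finite(weights$BETA) & weights$BETA != 0),
          "weights must be finite and nonzero")
  .assert(!anyDuplicated(weights$SNP), "weight SNP ids must be unique")
  flip <- weights$BETA < 0
  ea <- weights$EA
  weights$EA[flip] <- weights$OA[flip]
  weights$OA[flip] <- ea[flip]
  weights$BETA[flip] <- -weights$BETA[flip]
  if ("EAF" %in% names(weights)) weights$EAF[flip] <- 1 - weights$EAF[flip]
  weights
}

#' Build a weighted genetic risk score
#'
#' Per-subject score `sum_j beta_j * N_ij`, where `N_ij` is the dosage of
#' weight j's effect allele after harmonizing each weight to the panel's
#' allele labels (dosage flip `2 - g`, or strand complement, as needed).
#' Missing dosages are mean-imputed per variant.
#'
#' @param panel A [variant_panel()] containing every weight SNP.
#' @param weights Data.frame with columns `SNP`, `EA`, `OA`, `BETA`.
#' @return Numeric score vector (one per subject); attribute `"weights"`
#'   holds the harmonized weights actually applied.
#' @export
build_wgrs <- function(panel, weights) {
  .assert(inherits(panel, "variant_panel"), "panel must be a variant_panel")
  .assert(all(c("SNP", "EA", "OA", "BETA") %in% names(weights)),
          "weights need columns SNP, EA, OA, BETA")
  absent <- setdiff(weights$SNP, panel$variants$id)
  .assert(length(absent) == 0,
          paste("weight SNPs absent from panel:",
                paste(absent, collapse = ", ")))
  score <- numeric(nrow(panel$dosage))
  used <- weights
  for (k in seq_len(nrow(weights))) {
    w <- weights[k, ]
    vrow <- panel$variants[match(w$SNP, panel$variants$id), ]
    pan <- data.frame(EA = vrow$effect_allele, OA = vrow$other_allele)
    h <- .harmonize_row(pan, data.frame(EA = w$EA, OA = w$OA, BETA = 1))
    .assert(!is.null(h),
            paste0("allele mismatch for ", w$SNP,
                   " not resolvable by flip or complement"))
    g <- panel$dosage[, w$SNP]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (h$BETA < 0) g <- 2 - g   # weight allele is the panel's other allele
    score <- score + w$BETA * g
    used$EA[k] <- if (h$BETA < 0) vrow$other_allele else vrow$effect_allele
  }
  attr(score, "weights") <- used
  score
}

# Shared regression core: response ~ intercept + focal + covariates,
# returning the focal coefficient's estimate, se, t, P, and df.
.focal_ols <- function(response, focal, covariates, focal_name) {
  .assert(stats::sd(focal) > 0, paste(focal_name, "is constant"))
  n <- length(response)
  .assert(length(focal) == n, "misaligned inputs")
  X <- .design_matrix(covariates, n)
  X <- cbind(X[, 1, drop = FALSE],
             stats::setNames(data.frame(focal), focal_name),
             X[, -1, drop = FALSE])
  X <- as.matrix(X)
  fit <- .ols_fit(response, X)
  list(beta = unname(fit$coef[2]), se = unname(fit$se[2]),
       t = unname(fit$t[2]), p = unname(fit$p[2]), df = fit$df, n = n)
}

#' First-stage (instrument-exposure) regression
#'
#' OLS of the exposure on the genetic risk score, adjusted for covariates
#' (age and sex by convention). The instrument-strength F statistic is the
#' squared t statistic of the score coefficient.
#'
#' @param score Per-subject instrument (e.g. from [build_wgrs()]).
#' @param exposure Exposure vector (the prepared metabolite).
#' @param covariates Optional covariates, rows aligned.
#' @return List with `beta`, `se`, `p`, `F`, `df`, `n`.
#' @export
first_stage <- function(score, exposure, covariates = NULL) {
  fit <- .focal_ols(exposure, score, covariates, "score")
  fit$F <- fit$t^2
  fit
}

#' Reduced-form (instrument-outcome) regression
#'
#' @inheritParams first_stage
#' @param outcome Outcome trait vector.
#' @return List with `beta`, `se`, `p`, `df`, `n`.
#' @export
reduced_form <- function(score, outcome, covariates = NULL) {
  .focal_ols(outcome, score, covariates, "score")
}

#' Observational exposure-outcome regression
#'
#' OLS of the outcome on the exposure, adjusted for covariates; the
#' conventional (confounding-prone) estimate paired with the causal one.
#'
#' @param exposure,outcome Aligned trait vectors.
#' @param covariates Optional covariates.
#' @return List with `beta`, `se`, `p`, `df`, `n`.
#' @export
observational_estimate <- function(exposure, outcome, covariates = NULL) {
  .focal_ols(outcome, exposure, covariates, "exposure")
}

#' Wald-type (ratio) causal estimator
#'
#' `wald_beta = beta_ZY / beta_ZX`, with the delta-method standard error
#' `sqrt(se_ZY^2 / beta_ZX^2 + beta_ZY^2 se_ZX^2 / beta_ZX^4)` (second
#' order, first-stage uncertainty included; `method = "delta1"` gives the
#' first-order `se_ZY / |beta_ZX|`). 95% CI is `wald_beta +/- 1.96 se`;
#' two-sided P from the normal reference.
#'
#' @param beta_ZX,se_ZX Instrument-exposure estimate and SE (`beta_ZX != 0`).
#' @param beta_ZY,se_ZY Instrument-outcome estimate and SE.
#' @param method `"delta2"` (default) or `"delta1"`.
#' @return List with `wald_beta`, `wald_se`, `ci95` (length-2), `p`.
#' @export
#' @examples
#' wald_estimator(0.25, 0.03, 0.10, 0.05)
wald_estimator <- function(beta_ZX, se_ZX, beta_ZY, se_ZY,
                           method = c("delta2", "delta1")) {
  method <- match.arg(method)
  .assert(beta_ZX != 0, "beta_ZX must be nonzero (ratio undefined)")
  .assert(se_ZX > 0 && se_ZY > 0, "standard errors must be positive")
  if (abs(beta_ZX / se_ZX) < 1) {
    warning("weak instrument: |beta_ZX / se_ZX| < 1; ",
            "Wald interval is unreliable")
  }
  wald_beta <- beta_ZY / beta_ZX
  wald_se <- switch(method,
    delta2 = sqrt(se_ZY^2 / beta_ZX^2 + beta_ZY^2 * se_ZX^2 / beta_ZX^4),
    delta1 = se_ZY / abs(beta_ZX))
  ci <- wald_beta + c(-1, 1) * stats::qnorm(0.975) * wald_se
  list(wald_beta = wald_beta, wald_se = wald_se, ci95 = ci,
       p = .p_from_z(wald_beta / wald_se), method = method)
}

#' Pleiotropy / confounder check for the instrument
#'
#' Regresses the genetic risk score on each candidate confounder singly; a
#' valid instrument should show no association with measured confounders
#' such as age and sex.
#'
#' @param score Instrument vector.
#' @param confounders Data.frame of candidate confounders (may be empty).
#' @return Data.frame with one row per confounder: `beta`, `se`, `p`, `n`.
#' @export
pleiotropy_check <- function(score, confounders) {
  confounders <- as.data.frame(confounders)
  if (ncol(confounders) == 0) {
    return(data.frame(confounder = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), n = integer(0)))
  }
  out <- lapply(names(confounders), function(nm) {
    fit <- .focal_ols(score, as.numeric(confounders[[nm]]), NULL, nm)
    data.frame(confounder = nm, beta = fit$beta, se = fit$se, p = fit$p,
               n = fit$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sample Mendelian randomization with a weighted GRS instrument
#'
#' Builds the weighted genetic risk score, fits the instrument-exposure
#' regression (with its F statistic), and for each outcome the reduced-form
#' and observational regressions and the Wald-ratio causal estimate with
#' delta-method 95% CI — the paired observational/causal table a forest
#' plot is drawn from.
#'
#' @param panel A [variant_panel()].
#' @param pheno Phenotype data.frame aligned with the panel's subjects,
#'   containing the exposure, outcomes and covariates.
#' @param weights Instrument weights (`SNP`, `EA`, `OA`, `BETA`).
#' @param outcomes Character vector of outcome column names.
#' @param exposure Exposure column name (default `"metabolite"`) or a
#'   numeric vector (e.g. an inverse-normal prepared trait).
#' @param covariates Covariate column names for all regressions
#'   (default `c("age", "sex")`).
#' @param wald_method Passed to [wald_estimator()].
#' @return Object of class `mr_result`: `first_stage` (with F), `table`
#'   (one row per outcome: observational and causal estimates, CI, P, F, n)
#'   and `score`.
#' @export
run_mr <- function(panel, pheno, weights, outcomes,
                   exposure = "metabolite", covariates = c("age", "sex"),
                   wald_method = "delta2") {
  .assert(nrow(pheno) == nrow(panel$dosage),
          "phenotype rows do not match panel subjects")
  missing_cols <- setdiff(c(outcomes,
                            if (is.character(exposure)) exposure,
                            covariates), names(pheno))
  .assert(length(missing_cols) == 0,
          paste("phenotype table lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  x <- if (is.character(exposure)) pheno[[exposure]] else as.numeric(exposure)
  covs <- if (length(covariates)) pheno[covariates] else NULL
  score <- build_wgrs(panel, weights)
  fs <- first_stage(score, x, covs)
  rows <- lapply(outcomes, function(oc) {
    y <- pheno[[oc]]
    rf <- reduced_form(score, y, covs)
    obs <- observational_estimate(x, y, covs)
    wd <- wald_estimator(fs$beta, fs$se, rf$beta, rf$se,
                         method = wald_method)
    data.frame(outcome = oc,
               beta_obs = obs$beta, se_obs = obs$se, p_obs = obs$p,
               beta_causal = wd$wald_beta, se_causal = wd$wald_se,
               ci_low = wd$ci95[1], ci_high = wd$ci95[2],
               p_causal = wd$p, F = fs$F, n = fs$n,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(first_stage = fs, table = tab, score = score),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "One-sample MR (wGRS instrument): beta_ZX = %.*f (SE %.*f), F = %.2f, n = %d\n",
    digits, x$first_stage$beta, digits, x$first_stage$se,
    x$first_stage$F, x$first_stage$n))
  tab <- x$table
  fmt <- function(v) formatC(v, digits = digits, format = "fg")
  cat(sprintf("%-10s %12s %12s %22s %10s\n",
              "outcome", "obs beta", "obs P", "causal beta [95% CI]",
              "causal P"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-10s %12s %12.3g %9s [%s, %s] %10.3g\n",
                tab$outcome[i], fmt(tab$beta_obs[i]), tab$p_obs[i],
                fmt(tab$beta_causal[i]), fmt(tab$ci_low[i]),
                fmt(tab$ci_high[i]), tab$p_causal[i]))
  }
  invisible(x)
}
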