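# Independent oracles and small fixture builders used across the suite.

# Exact HWE probabilities by direct log-factorial enumeration (closed-form
# conditional pmf), independent of the package's ratio recurrence.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n - n_A
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hs, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- (max(n_A, n_a) - h) / 2
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[match(n_Aa, hs)] * (1 + 1e-10)]))
}

# Residuals of v on (intercept + C), by explicit normal equations.
resid_on <- function(v, C = NULL) {
  X <- cbind(1, C)
  drop(v - X %*% solve(crossprod(X), crossprod(X, v)))
}

# Single-instrument two-stage least squares via Frisch-Waugh-Lovell:
# partial the covariates out of the instrument, then take the ratio of
# instrument-outcome to instrument-exposure cross-products.
tsls_oracle <- function(y, x, z, covs = NULL) {
  zt <- resid_on(z, covs)
  sum(zt * y) / sum(zt * x)
}

# Simple OLS slope/se/p oracle for y ~ 1 + g, explicit formulas.
ols_slope_oracle <- function(y, g) {
  n <- length(y)
  X <- cbind(1, g)
  coef <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% coef
  sigma2 <- sum(res^2) / (n - 2)
  se <- unname(sqrt(diag(solve(crossprod(X))) * sigma2)[2])
  t <- unname(coef[2] / se)
  list(beta = unname(coef[2]), se = se, t = t,
       p = unname(2 * pt(-abs(t), n - 2)))
}

# Instrument weights derived from the default simulated architecture,
# oriented to the exposure-raising allele.
table2_weights <- function() {
  v <- default_instruments()
  orient_weights(data.frame(SNP = v$id, EA = v$effect_allele,
                            OA = v$other_allele, BETA = v$beta_metabolite,
                            stringsAsFactors = FALSE))
}

# Printed two-stage summary statistics for the four replicated variants
# (discovery and validation effects on the inverse-normalized metabolite).
published_two_stage <- function() {
  list(
    discovery = data.frame(
      SNP = c("rs12476238", "rs56146133", "rs2479714", "rs12229654"),
      EA = c("T", "G", "G", "G"), OA = c("C", "A", "A", "T"),
      BETA = c(-0.38, 0.21, -0.22, -0.21),
      SE = c(0.07, 0.05, 0.05, 0.05),
      P = c(8.99e-8, 4.01e-5, 3.61e-5, 4.85e-5),
      stringsAsFactors = FALSE),
    validation = data.frame(
      SNP = c("rs12476238", "rs56146133", "rs2479714", "rs12229654"),
      EA = c("T", "G", "G", "G"), OA = c("C", "A", "A", "T"),
      BETA = c(-0.29, 0.29, -0.25, -0.28),
      SE = c(0.14, 0.11, 0.11, 0.10),
      P = c(3.77e-2, 1.09e-2, 2.95e-2, 7.33e-3),
      stringsAsFactors = FALSE)
  )
}

# A one-variant configuration for focused genotype tests.
one_variant_config <- function(n, eaf, beta = 0, seed = 1, ...) {
  sim_config(
    n_subjects = n,
    variants = data.frame(id = "v1", chrom = "1", pos = 100L,
                          effect_allele = "A", other_allele = "G",
                          eaf = eaf, beta_metabolite = beta,
                          stringsAsFactors = FALSE),
    seed = seed, ...)
}
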