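make_panel <- function(D, ids = colnames(D), ea = "A", oa = "G") {
  variant_panel(data.frame(id = ids, chrom = "1",
                           pos = seq_along(ids) * 1000L,
                           effect_allele = ea, other_allele = oa,
                           stringsAsFactors = FALSE), D)
}

test_that("weighted GRS is the harmonized beta-weighted allele count", {
  w <- table2_weights()
  expect_true(all(w$BETA > 0))
  # four variants, every subject carrying two effect alleles
  co <- simulate_cohort(sim_config(n_subjects = 5, seed = 1))
  panel <- co$panel
  D <- panel$dosage
  D[] <- NA_real_
  # effect alleles in the panel are Table-2 A1; weights are raising-allele
  for (k in seq_len(nrow(w))) {
    raising_is_panel_ea <-
      w$EA[k] == panel$variants$effect_allele[match(w$SNP[k],
                                                    panel$variants$id)]
    D[, w$SNP[k]] <- if (raising_is_panel_ea) 2 else 0
  }
  panel2 <- variant_panel(panel$variants, D, panel$subjects)
  expect_equal(as.numeric(build_wgrs(panel2, w)),
               rep(2 * sum(w$BETA), 5), tolerance = 1e-12)
  expect_equal(2 * sum(w$BETA), 2.04)

  # all-zero raising dosage gives score zero
  D0 <- D
  D0[] <- 0
  w_ea <- w
  for (k in seq_len(nrow(w))) {  # align weights onto panel EA orientation
    vrow <- panel$variants[match(w$SNP[k], panel$variants$id), ]
    w_ea$EA[k] <- vrow$effect_allele
    w_ea$OA[k] <- vrow$other_allele
  }
  expect_equal(as.numeric(build_wgrs(variant_panel(panel$variants, D0),
                                     w_ea)),
               rep(0, 5))

  expect_error(build_wgrs(panel, transform(w, SNP = paste0(SNP, "_x"))),
               "absent")
})

test_that("allele-label flips in the weight file leave the score unchanged", {
  set.seed(61)
  D <- cbind(v1 = rbinom(100, 2, 0.3), v2 = rbinom(100, 2, 0.4))
  panel <- make_panel(D)
  w <- data.frame(SNP = c("v1", "v2"), EA = "A", OA = "G",
                  BETA = c(0.4, 0.2), stringsAsFactors = FALSE)
  w_flip <- w
  w_flip$EA[2] <- "G"
  w_flip$OA[2] <- "A"
  w_flip$BETA[2] <- -0.2
  s1 <- build_wgrs(panel, orient_weights(w))
  s2 <- build_wgrs(panel, orient_weights(w_flip))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)

  # a weight stated on the panel's other allele is flipped internally,
  # shifting the score by a constant that every regression absorbs
  x <- rnorm(100)
  w_v1 <- w[1, , drop = FALSE]
  w_v1_other <- data.frame(SNP = "v1", EA = "G", OA = "A", BETA = 0.4)
  s_a <- as.numeric(build_wgrs(panel, w_v1))
  s_b <- as.numeric(build_wgrs(panel, w_v1_other))
  expect_equal(sd(s_a - (2 * 0.4 - s_b)), 0, tolerance = 1e-12)
  expect_equal(abs(first_stage(s_a, x)$beta),
               abs(first_stage(s_b, x)$beta), tolerance = 1e-12)
  expect_equal(first_stage(s_a, x)$p, first_stage(s_b, x)$p,
               tolerance = 1e-12)
})

test_that("first stage reports F as the squared t of the score", {
  set.seed(62)
  n <- 300
  score <- rnorm(n)
  covs <- data.frame(age = rnorm(n, 57, 10), sex = rbinom(n, 1, 0.5))
  x <- 0.3 * score + rnorm(n)
  fs <- first_stage(score, x, covs)
  ref <- summary(lm(x ~ score + age + sex, data = cbind(covs, x, score)))
  expect_equal(fs$beta, coef(ref)["score", "Estimate"], tolerance = 1e-10)
  expect_equal(fs$se, coef(ref)["score", "Std. Error"], tolerance = 1e-10)
  expect_equal(fs$F, coef(ref)["score", "t value"]^2, tolerance = 1e-8)
  expect_error(first_stage(rep(1, n), x), "constant")
})

test_that("null first-stage F has mean near one", {
  set.seed(63)
  Fs <- replicate(200, {
    first_stage(rnorm(100), rnorm(100))$F
  })
  expect_gt(mean(Fs), 0.75)
  expect_lt(mean(Fs), 1.35)
})

test_that("reduced form and observational estimates follow the linear SEM", {
  co <- simulate_cohort(sim_config(n_subjects = 20000, theta = 0.5,
                                   confounder_effect = 0, seed = 64))
  covs <- co$pheno[c("age", "sex")]
  score <- build_wgrs(co$panel, table2_weights())
  fs <- first_stage(score, co$pheno$metabolite, covs)
  rf <- reduced_form(score, co$pheno$bmi, covs)
  expect_equal(rf$beta / fs$beta, 0.5, tolerance = 0.1)

  obs <- observational_estimate(co$pheno$metabolite, co$pheno$bmi, covs)
  expect_equal(obs$beta, 0.5, tolerance = 0.05)

  y <- co$pheno$metabolite
  expect_equal(reduced_form(score, y, covs)$beta, fs$beta, tolerance = 1e-12)
  expect_equal(observational_estimate(y, y)$beta, 1, tolerance = 1e-12)
})

test_that("Wald estimator has its closed form and ratio invariances", {
  expect_equal(wald_estimator(0.25, 0.03, 0, 0.05)$wald_beta, 0)
  wd <- wald_estimator(0.25, 0.03, 0.10, 0.05)
  expect_equal(wd$wald_beta, 0.4)
  expect_equal(wd$wald_se,
               sqrt(0.05^2 / 0.25^2 + 0.10^2 * 0.03^2 / 0.25^4),
               tolerance = 1e-12)
  expect_equal(wd$wald_se, 0.2056794, tolerance = 1e-6)
  expect_equal(wd$ci95, wd$wald_beta + c(-1, 1) * qnorm(0.975) * wd$wald_se)

  # parametric-bootstrap oracle for the delta-method SE
  set.seed(65)
  bzx <- rnorm(1e5, 0.25, 0.03)
  bzy <- rnorm(1e5, 0.10, 0.05)
  expect_equal(sd(bzy / bzx), wd$wald_se, tolerance = 0.1)

  # rescaling the instrument leaves the ratio unchanged
  wd2 <- wald_estimator(0.25 / 3, 0.03 / 3, 0.10 / 3, 0.05 / 3)
  expect_equal(wd2$wald_beta, wd$wald_beta, tolerance = 1e-12)
  expect_equal(wd2$wald_se, wd$wald_se, tolerance = 1e-12)

  expect_equal(wald_estimator(0.25, 0.03, 0.1, 0.05,
                              method = "delta1")$wald_se, 0.05 / 0.25)
  expect_error(wald_estimator(0, 0.03, 0.1, 0.05), "nonzero")
  expect_warning(wald_estimator(0.02, 0.03, 0.1, 0.05), "weak instrument")
})

test_that("Wald ratio equals single-instrument 2SLS", {
  set.seed(66)
  for (i in 1:10) {
    n <- 400
    z <- rbinom(n, 2, runif(1, 0.1, 0.45))
    covs <- cbind(age = rnorm(n, 57, 10), sex = rbinom(n, 1, 0.5))
    u <- rnorm(n)
    x <- 0.4 * z + 0.01 * covs[, "age"] + 0.5 * u + rnorm(n)
    y <- 0.6 * x + 0.5 * u + rnorm(n)
    fs <- first_stage(z, x, covs)
    rf <- reduced_form(z, y, covs)
    wd <- suppressWarnings(wald_estimator(fs$beta, fs$se, rf$beta, rf$se))
    expect_equal(wd$wald_beta, tsls_oracle(y, x, z, covs),
                 tolerance = 1e-8)
  }
})

test_that("pleiotropy check flags only genuine score-confounder association", {
  set.seed(67)
  age <- rnorm(500, 57, 10)
  out <- pleiotropy_check(age, data.frame(age = age))
  expect_equal(out$p, 1e-300)
  empty <- pleiotropy_check(rnorm(10), data.frame())
  expect_equal(nrow(empty), 0)

  hits <- 0L
  for (s in 1:20) {
    co <- simulate_cohort(sim_config(n_subjects = 300, seed = 200 + s))
    score <- build_wgrs(co$panel, table2_weights())
    pl <- pleiotropy_check(score, co$pheno[c("age", "sex")])
    hits <- hits + sum(pl$p < 0.05)
  }
  expect_lte(hits / 40, 0.25)
})

test_that("run_mr assembles the paired observational/causal table", {
  co <- simulate_cohort(sim_config(n_subjects = 800, theta = 0.4, seed = 68))
  fit <- run_mr(co$panel, co$pheno, table2_weights(),
                outcomes = c("bmi", "homa_ir"))
  expect_s3_class(fit, "mr_result")
  expect_identical(fit$table$outcome, c("bmi", "homa_ir"))
  expect_true(all(fit$table$ci_low < fit$table$beta_causal))
  expect_true(all(fit$table$ci_high > fit$table$beta_causal))
  expect_equal(fit$table$F, rep(fit$first_stage$F, 2))

  # outcome identical to the exposure gives a unit causal effect exactly
  ph <- co$pheno
  ph$bmi <- ph$metabolite
  fit1 <- run_mr(co$panel, ph, table2_weights(), outcomes = "bmi")
  expect_equal(fit1$table$beta_causal, 1, tolerance = 1e-12)

  expect_error(run_mr(co$panel, co$pheno, table2_weights(),
                      outcomes = "not_a_trait"), "not_a_trait")
})
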