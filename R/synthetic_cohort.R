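#' Instrument variants used as simulation defaults
#'
#' The four replicated gamma-glutamyl-leucine variants, with their
#' chromosome, hg19 position, effect (A1) and other allele, effect-allele
#' frequency and per-allele effect on the inverse-normalized metabolite
#' (SD units). These define the default genetic architecture of the
#' synthetic cohort.
#'
#' @return A data.frame with columns `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_metabolite`.
#' @export
#' @examples
#' default_instruments()
default_instruments <- function() {
  data.frame(
    id = c("rs12476238", "rs56146133", "rs12229654", "rs2479714"),
    chrom = c("2", "3", "12", "13"),
    pos = c(108940336L, 152513774L, 111414461L, 107715021L),
    effect_allele = c("T", "G", "G", "G"),
    other_allele = c("C", "A", "T", "A"),
    eaf = c(0.11, 0.22, 0.25, 0.75),
    beta_metabolite = c(-0.38, 0.21, -0.21, -0.22),
    stringsAsFactors = FALSE
  )
}

#' Names of the simulated cardio-metabolic outcome traits
#' @return Character vector of the 13 outcome column names.
#' @export
outcome_traits <- function() {
  c("bmi", "wc", "whr", "sbp", "dbp", "tg", "tc", "ldl", "hdl",
    "ua", "insulin", "glucose", "homa_ir")
}

# Location/scale used when outcomes are mapped onto measurement units for
# cosmetic realism. Locations follow the discovery-cohort characteristics;
# dispersions are field-typical values (the source table reports medians and
# interquartile ranges for several traits, which do not pin down an SD).
.trait_scale_map <- function() {
  data.frame(
    trait = outcome_traits(),
    mean = c(24.46, 82.64, 0.87, 140.6, 83.56, 1.66, 4.74, 2.16, 1.5,
             5.75, 3.9, 5.14, 0.92),
    sd = c(3.5, 10, 0.06, 20, 11, 1.0, 0.9, 0.7, 0.35, 1.4, 3.0, 1.1, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a synthetic genotype/phenotype cohort
#'
#' Defaults reproduce the discovery-stage study conditions: 1,062 subjects,
#' the four instrument variants of [default_instruments()] with their
#' effect-allele frequencies and per-allele effects in SD units, age
#' ~ Normal(57.4, 10) years, half male, unit-variance metabolite residual,
#' and a common causal effect `theta` of the metabolite on every outcome.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param variants Data.frame of causal variants (columns `id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta_metabolite`).
#'   `eaf` is the effect-allele frequency in (0, 1).
#' @param n_null_variants Number of effect-free variants, arranged in LD
#'   blocks on chromosome 1.
#' @param ld_block_r Target pairwise dosage correlation within a null-variant
#'   LD block, in \[0, 1).
#' @param ld_block_size Number of variants per LD block.
#' @param theta Causal effect of the (standardized) metabolite on each
#'   outcome, SD per SD. Scalar, or named vector over [outcome_traits()].
#' @param confounder_effect Effect of a latent standard-normal confounder U
#'   on the metabolite and on every outcome (same coefficient on both, the
#'   classic shared-cause bias).
#' @param gamma_age,gamma_sex Covariate effects on the metabolite, in SD per
#'   SD of age and per unit of sex respectively.
#' @param age_mean,age_sd Age distribution, years.
#' @param sex_fraction Proportion of males (sex coded 1).
#' @param metabolite_noise_sd Residual SD of the metabolite.
#' @param noise_sd Residual SD of each outcome trait.
#' @param null_maf_range MAF range for null variants (drawn uniformly).
#' @param missing_rate Probability that any dosage entry is masked missing.
#' @param n_pcs Number of genetic principal-component covariate columns
#'   (simulated as standard-normal noise; no stratification structure).
#' @param outcome_scale `"standardized"` leaves outcomes on the SD scale the
#'   generative model uses; `"mapped"` affinely rescales each trait to a
#'   realistic measurement-unit location/scale. Causal and instrumental
#'   estimates are equivariant to this choice.
#' @param seed Integer RNG seed; all simulation is deterministic given it.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 200, seed = 7)
#' cfg$variants$id
sim_config <- function(n_subjects = 1062,
                       variants = default_instruments(),
                       n_null_variants = 0,
                       ld_block_r = 0.8,
                       ld_block_size = 5,
                       theta = 0.3,
                       confounder_effect = 0,
                       gamma_age = 0.1,
                       gamma_sex = 0.1,
                       age_mean = 57.4,
                       age_sd = 10,
                       sex_fraction = 0.5,
                       metabolite_noise_sd = 1,
                       noise_sd = 1,
                       null_maf_range = c(0.05, 0.5),
                       missing_rate = 0,
                       n_pcs = 2,
                       outcome_scale = c("standardized", "mapped"),
                       seed = 1L) {
  outcome_scale <- match.arg(outcome_scale)
  .assert(n_subjects >= 2, "n_subjects must be at least 2")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta_metabolite")
  .assert(all(needed %in% names(variants)),
          paste("variants must have columns:", paste(needed, collapse = ", ")))
  .assert(!anyDuplicated(variants$id), "variant ids must be unique")
  .assert(all(variants$eaf > 0 & variants$eaf < 1),
          "effect-allele frequencies must lie strictly in (0, 1)")
  .assert(all(pmin(variants$eaf, 1 - variants$eaf) <= 0.5),
          "minor allele frequency must be in (0, 0.5]")
  .assert(ld_block_r >= 0 && ld_block_r < 1, "ld_block_r must be in [0, 1)")
  .assert(n_null_variants >= 0, "n_null_variants must be non-negative")
  .assert(missing_rate >= 0 && missing_rate < 1,
          "missing_rate must be in [0, 1)")
  .assert(all(null_maf_range > 0 & null_maf_range <= 0.5),
          "null_maf_range must lie in (0, 0.5]")
  traits <- outcome_traits()
  if (length(theta) == 1L && is.null(names(theta))) {
    theta <- stats::setNames(rep(theta, length(traits)), traits)
  } else {
    .assert(all(traits %in% names(theta)),
            "named theta must cover every outcome trait")
    theta <- theta[traits]
  }
  structure(list(
    n_subjects = as.integer(n_subjects), variants = variants,
    n_null_variants = as.integer(n_null_variants),
    ld_block_r = ld_block_r, ld_block_size = as.integer(ld_block_size),
    theta = theta, confounder_effect = confounder_effect,
    gamma_age = gamma_age, gamma_sex = gamma_sex,
    age_mean = age_mean, age_sd = age_sd, sex_fraction = sex_fraction,
    metabolite_noise_sd = metabolite_noise_sd, noise_sd = noise_sd,
    null_maf_range = null_maf_range, missing_rate = missing_rate,
    n_pcs = as.integer(n_pcs), outcome_scale = outcome_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# ---- variant panel container -------------------------------------------

#' Construct a variant panel
#'
#' A variant panel couples per-variant metadata with a subjects-by-variants
#' effect-allele dosage matrix (entries in \[0, 2\], NA where masked).
#'
#' @param variants Data.frame with at least `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`.
#' @param dosage Numeric matrix, one row per subject, one column per variant;
#'   columns named by variant id.
#' @param subjects Character vector of subject ids (defaults to rownames of
#'   `dosage` or `s1..sn`).
#' @return An object of class `variant_panel`.
#' @export
variant_panel <- function(variants, dosage, subjects = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  .assert(ncol(dosage) == nrow(variants),
          "dosage column count must equal variant record count")
  .assert(!anyDuplicated(variants$id), "variant ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1])) {
    .assert(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2] or be NA")
  }
  if (is.null(subjects)) {
    subjects <- rownames(dosage) %||% paste0("s", seq_len(nrow(dosage)))
  }
  .assert(length(subjects) == nrow(dosage),
          "subject ids must match dosage rows")
  dimnames(dosage) <- list(subjects, variants$id)
  structure(list(variants = variants, dosage = dosage,
                 subjects = as.character(subjects)),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a variant panel by variant id
#' @param panel A `variant_panel`.
#' @param ids Variant ids to keep (order preserved).
#' @return A `variant_panel` restricted to `ids`.
#' @export
subset_panel <- function(panel, ids) {
  missing_ids <- setdiff(ids, panel$variants$id)
  .assert(length(missing_ids) == 0,
          paste("variants absent from panel:",
                paste(missing_ids, collapse = ", ")))
  idx <- match(ids, panel$variants$id)
  variant_panel(panel$variants[idx, , drop = FALSE],
                panel$dosage[, idx, drop = FALSE], panel$subjects)
}

# ---- latent-Gaussian LD calibration ------------------------------------

# P(Z1 < q, Z2 < q) for standard bivariate normal with correlation rho,
# by 1-D quadrature of the conditional CDF.
.binorm_lower <- function(q, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(q)^2)
  f <- function(z) {
    stats::pnorm((q - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
  }
  stats::integrate(f, -Inf, q, rel.tol = 1e-10)$value
}

# Latent correlation such that two alleles thresholded at qnorm(p) have
# Pearson correlation r_target. Dosages (sums of two independent haplotypes)
# then inherit the same correlation.
.latent_corr_for_r <- function(r_target, p) {
  if (r_target <= 0) return(0)
  q <- stats::qnorm(p)
  pearson <- function(rho) {
    (.binorm_lower(q, rho) - p^2) / (p * (1 - p)) - r_target
  }
  stats::uniroot(pearson, c(0, 0.99999), tol = 1e-9)$root
}

# ---- genotype simulation ------------------------------------------------

#' Simulate hard-call genotypes for a synthetic cohort
#'
#' Causal variants are drawn independently from Hardy-Weinberg proportions at
#' their configured effect-allele frequencies. Null variants are arranged in
#' LD blocks on chromosome 1: within a block, haplotype alleles are generated
#' by thresholding an exchangeable latent Gaussian whose correlation is
#' calibrated so the realized dosage correlation matches `ld_block_r`.
#'
#' @param config A [sim_config()].
#' @return A [variant_panel()] with hard-call dosages in \{0, 1, 2\} (NA where
#'   masked by `missing_rate`). Deterministic given `config$seed`.
#' @export
#' @examples
#' panel <- simulate_genotypes(sim_config(n_subjects = 50, seed = 1))
#' dim(panel$dosage)
simulate_genotypes <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_subjects
  v <- config$variants

  dosage <- vapply(v$eaf, function(p) as.numeric(stats::rbinom(n, 2L, p)),
                   numeric(n))
  variants <- v[, c("id", "chrom", "pos", "effect_allele", "other_allele")]

  m0 <- config$n_null_variants
  if (m0 > 0) {
    b <- config$ld_block_size
    block_of <- ceiling(seq_len(m0) / b)
    n_blocks <- max(block_of)
    null_dos <- matrix(0, n, m0)
    mafs <- numeric(m0)
    for (blk in seq_len(n_blocks)) {
      cols <- which(block_of == blk)
      maf <- stats::runif(1, config$null_maf_range[1], config$null_maf_range[2])
      mafs[cols] <- maf
      rho <- .latent_corr_for_r(config$ld_block_r, maf)
      q <- stats::qnorm(maf)
      g <- matrix(0L, n, length(cols))
      for (hap in 1:2) {
        common <- stats::rnorm(n)
        z <- sqrt(rho) * common +
          sqrt(1 - rho) * matrix(stats::rnorm(n * length(cols)), n)
        g <- g + (z < q)
      }
      null_dos[, cols] <- g
    }
    null_meta <- data.frame(
      id = sprintf("null_%05d", seq_len(m0)),
      chrom = "1",
      # blocks are 1 Mb apart so they are clump-independent; variants within
      # a block sit 5 kb apart, well inside the clump window
      pos = as.integer(1e6 * block_of + 5e3 * (seq_len(m0) - 1L)),
      effect_allele = "A", other_allele = "G",
      stringsAsFactors = FALSE
    )
    dosage <- cbind(dosage, null_dos)
    variants <- rbind(variants, null_meta)
  }

  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dosage)) < config$missing_rate,
                   nrow(dosage))
    dosage[mask] <- NA_real_
  }
  variant_panel(variants, dosage,
                subjects = sprintf("subj_%05d", seq_len(n)))
}

# ---- phenotype simulation ----------------------------------------------

#' Simulate phenotypes for a genotyped synthetic cohort
#'
#' The metabolite follows a linear structural model: per-allele genetic
#' effects plus age/sex covariate effects, a latent standard-normal
#' confounder U scaled by `confounder_effect`, and Gaussian noise. Each
#' outcome trait receives `theta` times the metabolite plus the same
#' confounder and its own noise. The realized ground truth (including U) is
#' attached as attribute `"truth"` for parameter-recovery tests.
#'
#' @param panel A [variant_panel()] from [simulate_genotypes()] under the
#'   same config.
#' @param config The same [sim_config()].
#' @return A data.frame (class `pheno_table`) with columns `subject_id`,
#'   `age`, `sex`, principal-component columns, `metabolite`, and the 13
#'   outcome traits; attribute `"truth"` holds the generative parameters.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 100, seed = 2)
#' ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' names(ph)
simulate_phenotypes <- function(panel, config) {
  .assert(inherits(panel, "variant_panel"), "panel must be a variant_panel")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  n <- config$n_subjects
  .assert(nrow(panel$dosage) == n,
          "panel subject count does not match config$n_subjects")
  set.seed(config$seed + 1L)

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$sex_fraction)
  U <- stats::rnorm(n)
  pcs <- if (config$n_pcs > 0) {
    matrix(stats::rnorm(n * config$n_pcs), n,
           dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))
  }

  v <- config$variants
  G <- panel$dosage[, v$id, drop = FALSE]
  # mean-impute any masked dosages for the generative sum
  if (anyNA(G)) {
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  genetic <- drop(G %*% v$beta_metabolite)
  age_std <- (age - config$age_mean) / config$age_sd
  metabolite <- genetic + config$gamma_age * age_std +
    config$gamma_sex * sex + config$confounder_effect * U +
    stats::rnorm(n, 0, config$metabolite_noise_sd)

  traits <- outcome_traits()
  out <- matrix(NA_real_, n, length(traits),
                dimnames = list(NULL, traits))
  for (tr in traits) {
    out[, tr] <- config$theta[[tr]] * metabolite +
      config$confounder_effect * U + stats::rnorm(n, 0, config$noise_sd)
  }
  if (config$outcome_scale == "mapped") {
    sm <- .trait_scale_map()
    for (k in seq_len(nrow(sm))) {
      tr <- sm$trait[k]
      out[, tr] <- sm$mean[k] + sm$sd[k] * out[, tr]
    }
  }

  ph <- data.frame(subject_id = panel$subjects, age = age, sex = sex,
                   stringsAsFactors = FALSE)
  if (!is.null(pcs)) ph <- cbind(ph, as.data.frame(pcs))
  ph$metabolite <- metabolite
  ph <- cbind(ph, as.data.frame(out))
  for (tr in traits) {
    .assert(stats::sd(ph[[tr]]) > 0, "simulated outcome is constant")
  }
  attr(ph, "truth") <- list(
    config = config, U = U, genetic_component = genetic,
    beta_metabolite = stats::setNames(v$beta_metabolite, v$id),
    theta = config$theta
  )
  class(ph) <- c("pheno_table", "data.frame")
  ph
}

#' Simulate a complete cohort (genotypes + phenotypes)
#' @inheritParams simulate_phenotypes
#' @param config A [sim_config()].
#' @return List with elements `panel` and `pheno`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_genotypes(config)
  list(panel = panel, pheno = simulate_phenotypes(panel, config))
}
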