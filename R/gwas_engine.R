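#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts: given the allele counts, the
#' P value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count. The
#' distribution is evaluated by the standard ratio recurrence over
#' heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return Exact two-sided P value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(100, 0, 0) # monomorphic: 1
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  .assert(all(c(n_AA, n_Aa, n_aa) >= 0), "genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  .assert(n >= 1, "at least one genotype required")
  n_a <- 2 * n_aa + n_Aa                 # allele counts
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1.0)
  h_obs <- n_Aa
  hs <- seq(rare %% 2, rare, by = 2)     # feasible heterozygote counts
  lw <- numeric(length(hs))              # log weights: recurrence kept in
  if (length(hs) > 1) {                  # log space to avoid overflow
    for (k in seq_len(length(hs) - 1L)) {
      h <- hs[k]
      hom_rare <- (rare - h) / 2
      hom_common <- (max(n_A, n_a) - h) / 2
      # w(h+2)/w(h) from the conditional probability mass function
      lw[k + 1L] <- lw[k] + log(4 * hom_rare * hom_common) -
        log((h + 1) * (h + 2))
    }
  }
  w <- exp(lw - max(lw))
  prob <- w / sum(w)
  p_obs <- prob[match(h_obs, hs)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

#' Variant quality-control filter
#'
#' Retains variants passing all of: minor allele frequency >= `maf_min`,
#' Hardy-Weinberg exact P >= `hwe_p_min`, and call rate >= `call_rate_min`.
#' Hard-call genotype counts for the HWE test are taken from rounded
#' dosages.
#'
#' @param panel A [variant_panel()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param hwe_p_min Minimum HWE exact P (default 1e-4).
#' @param call_rate_min Minimum per-variant call rate (default 0.95).
#' @return List with `panel` (the filtered panel) and `log`, a data.frame
#'   with per-variant `maf`, `hwe_p`, `call_rate`, `kept`, and the
#'   comma-separated exclusion `reason` for dropped variants.
#' @export
filter_variants <- function(panel, maf_min = 0.05, hwe_p_min = 1e-4,
                            call_rate_min = 0.95) {
  .assert(inherits(panel, "variant_panel"), "panel must be a variant_panel")
  .assert(ncol(panel$dosage) >= 1, "panel is empty")
  D <- panel$dosage
  call_rate <- colMeans(!is.na(D))
  eaf <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  hwe_p <- vapply(seq_len(ncol(D)), function(j) {
    g <- round(D[!is.na(D[, j]), j])
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  reasons <- mapply(function(m, h, cr) {
    r <- c(if (is.na(m) || m < maf_min) "maf",
           if (h < hwe_p_min) "hwe",
           if (cr < call_rate_min) "call_rate")
    paste(r, collapse = ",")
  }, maf, hwe_p, call_rate)
  kept <- reasons == ""
  log <- data.frame(id = panel$variants$id, maf = maf, hwe_p = hwe_p,
                    call_rate = call_rate, kept = kept, reason = reasons,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(kept)) warning("no variants pass the QC filters")
  filtered <- variant_panel(panel$variants[kept, , drop = FALSE],
                            D[, kept, drop = FALSE], panel$subjects)
  list(panel = filtered, log = log)
}

#' Additive-model association scan
#'
#' Per-variant simple linear regression of a prepared trait on effect-allele
#' dosage (covariates are removed upstream by [prepare_trait()]):
#' `beta = cov(g, y) / var(g)`, standard error from the residual variance,
#' two-sided P from the t distribution with n - 2 degrees of freedom.
#' Missing dosages are handled per variant by complete-case analysis.
#'
#' @param panel A [variant_panel()].
#' @param trait Prepared numeric trait vector aligned with the panel's
#'   subjects.
#' @param min_n Minimum per-variant complete-case sample size (default 10);
#'   variants below it, or with zero dosage variance, are skipped and listed
#'   in the `"skipped"` attribute.
#' @return Data.frame with the summary-statistic columns `SNP`, `CHR`,
#'   `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `STAT`, `P`, `N`. P values are
#'   floored at 1e-300.
#' @export
assoc_scan <- function(panel, trait, min_n = 10) {
  .assert(inherits(panel, "variant_panel"), "panel must be a variant_panel")
  .assert(is.numeric(trait) && length(trait) == nrow(panel$dosage),
          "trait must be numeric and aligned with panel subjects")
  .assert(!anyNA(trait), "trait must not contain NA (prepare it first)")
  G <- panel$dosage
  y <- as.numeric(trait)
  obs <- !is.na(G)
  n <- colSums(obs)
  Gz <- G
  Gz[!obs] <- 0
  Sx <- colSums(Gz)
  Sxx <- colSums(Gz^2)
  Sxy <- colSums(Gz * y)
  Sy <- colSums(obs * y)
  Syy <- colSums(obs * y^2)
  Sxx_c <- Sxx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  usable <- n >= min_n & Sxx_c > 1e-12
  beta <- Sxy_c / Sxx_c
  sse <- pmax(Syy_c - beta^2 * Sxx_c, 0)
  df <- n - 2
  se <- sqrt(sse / df / Sxx_c)
  stat <- beta / se
  p <- .p_from_t(stat, df)
  out <- data.frame(
    SNP = panel$variants$id, CHR = panel$variants$chrom,
    POS = panel$variants$pos, EA = panel$variants$effect_allele,
    OA = panel$variants$other_allele, EAF = Sx / (2 * n),
    BETA = beta, SE = se, STAT = stat, P = p, N = n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  skipped <- out$SNP[!usable]
  out <- out[usable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(chi-square statistics) / qchisq(0.5, 1)`. When P values
#' are supplied, the 1-df chi-square statistics are recovered through the
#' quantile function.
#'
#' @param p Two-sided P values in (0, 1] (used when `statistic` is NULL).
#' @param statistic Optional 1-df chi-square statistics (e.g. squared
#'   t/z statistics).
#' @return The inflation factor lambda.
#' @export
#' @examples
#' genomic_inflation(statistic = rep(qchisq(0.5, 1), 5)) # exactly 1
genomic_inflation <- function(p = NULL, statistic = NULL) {
  if (is.null(statistic)) {
    .assert(!is.null(p) && length(p) >= 1, "supply p or statistic")
    .assert(all(p > 0 & p <= 1), "P values must lie in (0, 1]")
    statistic <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  .assert(length(statistic) >= 1, "at least one test required")
  stats::median(statistic) / stats::qchisq(0.5, df = 1)
}

#' Quantile-quantile plot coordinates
#'
#' @param results Association results (data.frame with column `P`).
#' @return Data.frame of `expected` and `observed` -log10(P), sorted with
#'   the strongest association last; `expected_i = -log10((i - 0.5) / m)`.
#' @export
qq_data <- function(results) {
  .assert(nrow(results) >= 1, "results must be nonempty")
  m <- nrow(results)
  p_sorted <- sort(results$P, decreasing = TRUE)
  i <- m:1
  data.frame(expected = -log10((i - 0.5) / m),
             observed = -log10(p_sorted))
}

#' Manhattan plot coordinates
#'
#' Adds a cumulative genome coordinate: chromosomes are laid end to end in
#' natural order and each variant's position is offset by the preceding
#' chromosomes' spans.
#'
#' @param results Association results with columns `CHR`, `POS`, `P`.
#' @return Input rows (sorted by chromosome and position) plus
#'   `genome_pos` and `neg_log10_p` columns.
#' @export
manhattan_data <- function(results) {
  .assert(nrow(results) >= 1, "results must be nonempty")
  chr <- as.character(results$CHR)
  chr_num <- suppressWarnings(as.numeric(chr))
  lev <- unique(chr[order(chr_num, chr)])
  o <- order(match(chr, lev), results$POS)
  res <- results[o, , drop = FALSE]
  span <- tapply(res$POS, factor(as.character(res$CHR), levels = lev), max)
  offset <- stats::setNames(c(0, cumsum(as.numeric(span))[-length(span)]), lev)
  res$genome_pos <- res$POS + offset[as.character(res$CHR)]
  res$neg_log10_p <- -log10(res$P)
  rownames(res) <- NULL
  res
}

#' Null-cohort GWAS calibration
#'
#' Simulates a homogeneous null cohort — independent Hardy-Weinberg variants
#' and a pure-noise phenotype put through inverse-normal preparation — and
#' runs the association scan, reporting the genomic inflation factor and the
#' empirical type-I error rate. Variants are generated and scanned in
#' chunks so memory stays flat at large variant counts.
#'
#' @param n_subjects Cohort size (default 1000).
#' @param n_variants Number of independent null variants (default 100000).
#' @param seed RNG seed.
#' @param maf_range Variant MAFs are drawn uniformly from this range.
#' @param chunk_size Variants simulated per chunk.
#' @param alpha Nominal level for the type-I error rate (default 0.05).
#' @return List with `lambda`, `type1_rate`, `n_subjects`, `n_variants`.
#' @export
null_gwas_calibration <- function(n_subjects = 1000, n_variants = 100000,
                                  seed = 1, maf_range = c(0.05, 0.5),
                                  chunk_size = 5000, alpha = 0.05) {
  set.seed(seed)
  y <- prepare_trait(stats::rnorm(n_subjects))
  stats_all <- numeric(0)
  p_all <- numeric(0)
  done <- 0L
  while (done < n_variants) {
    m <- min(chunk_size, n_variants - done)
    mafs <- stats::runif(m, maf_range[1], maf_range[2])
    G <- vapply(mafs, function(p) as.numeric(stats::rbinom(n_subjects, 2L, p)),
                numeric(n_subjects))
    vmeta <- data.frame(
      id = sprintf("nv_%07d", done + seq_len(m)), chrom = "1",
      pos = done + seq_len(m), effect_allele = "A", other_allele = "G",
      stringsAsFactors = FALSE
    )
    res <- assoc_scan(variant_panel(vmeta, G), y)
    stats_all <- c(stats_all, res$STAT^2)
    p_all <- c(p_all, res$P)
    done <- done + m
  }
  list(lambda = genomic_inflation(statistic = stats_all),
       type1_rate = mean(p_all < alpha),
       n_subjects = n_subjects, n_variants = n_variants)
}
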