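#' Pairwise linkage disequilibrium r-squared between dosage vectors
#'
#' Squared Pearson correlation of the two dosage vectors over pairwise
#' complete cases; invariant to allele-label flips (`g -> 2 - g`).
#'
#' @param dosage_a,dosage_b Equal-length numeric dosage vectors, each
#'   non-constant.
#' @return r^2 in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  .assert(length(dosage_a) == length(dosage_b),
          "dosage vectors must have equal length")
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  .assert(stats::sd(a) > 0 && stats::sd(b) > 0,
          "dosage vector is constant; r2 undefined")
  stats::cor(a, b)^2
}

#' Greedy LD clumping of association signals
#'
#' PLINK-style clumping: repeatedly take the lowest-P unassigned variant
#' with `P < p_suggestive` as an index, and absorb into its clump every
#' unassigned variant on the same chromosome within `window_bp` of it whose
#' in-sample LD with the index reaches `r2_max` (boundary absorbs,
#' i.e. r^2 >= r2_max). Indices are returned in P order.
#'
#' @param results Association results ([assoc_scan()] columns).
#' @param panel A [variant_panel()] providing dosages for every suggestive
#'   variant (in-sample LD reference).
#' @param window_bp Half-window in base pairs around the index
#'   (default 1e6, i.e. "1 Mb").
#' @param r2_max LD threshold; variants at or above it are absorbed
#'   (default 0.5).
#' @param p_suggestive P threshold for clump formation (default 5e-5).
#' @return List of class `clump_result`: `index` (rows of `results` for the
#'   index variants, in P order) and `membership` (data.frame mapping each
#'   suggestive variant to its index).
#' @export
clump <- function(results, panel, window_bp = 1e6, r2_max = 0.5,
                  p_suggestive = 5e-5) {
  .assert(window_bp > 0, "window must be positive")
  .assert(r2_max > 0 && r2_max < 1, "r2_max must be in (0, 1)")
  cand <- results[results$P < p_suggestive, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(structure(list(index = cand,
                          membership = data.frame(SNP = character(0),
                                                  index_SNP = character(0))),
                     class = "clump_result"))
  }
  missing_ids <- setdiff(cand$SNP, panel$variants$id)
  .assert(length(missing_ids) == 0,
          paste("suggestive variants absent from LD panel:",
                paste(missing_ids, collapse = ", ")))
  cand <- cand[order(cand$P), , drop = FALSE]
  assigned <- rep(FALSE, nrow(cand))
  index_rows <- integer(0)
  member_of <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (assigned[i]) next
    index_rows <- c(index_rows, i)
    assigned[i] <- TRUE
    member_of[i] <- cand$SNP[i]
    g_idx <- panel$dosage[, cand$SNP[i]]
    near <- which(!assigned &
                    as.character(cand$CHR) == as.character(cand$CHR[i]) &
                    abs(cand$POS - cand$POS[i]) <= window_bp)
    for (j in near) {
      if (ld_r2(g_idx, panel$dosage[, cand$SNP[j]]) >= r2_max) {
        assigned[j] <- TRUE
        member_of[j] <- cand$SNP[i]
      }
    }
  }
  structure(list(
    index = {x <- cand[index_rows, , drop = FALSE]; rownames(x) <- NULL; x},
    membership = data.frame(SNP = cand$SNP, index_SNP = member_of,
                            row.names = NULL, stringsAsFactors = FALSE)
  ), class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d index variant(s), %d suggestive variant(s)\n",
              nrow(x$index), nrow(x$membership)))
  invisible(x)
}

# Harmonize a validation row onto the discovery effect allele. Returns the
# (possibly sign-flipped) validation row, or NULL if alleles cannot be
# reconciled by swap or strand complement.
.harmonize_row <- function(disc, valid) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  same <- function(ea, oa) ea == disc$EA && oa == disc$OA
  swapped <- function(ea, oa) ea == disc$OA && oa == disc$EA
  ea <- valid$EA; oa <- valid$OA
  if (same(ea, oa)) return(valid)
  if (swapped(ea, oa)) {
    valid$BETA <- -valid$BETA
    if ("EAF" %in% names(valid)) valid$EAF <- 1 - valid$EAF
    valid$EA <- disc$EA; valid$OA <- disc$OA
    return(valid)
  }
  ea_c <- unname(comp[ea]); oa_c <- unname(comp[oa])
  if (!is.na(ea_c) && !is.na(oa_c)) {
    if (same(ea_c, oa_c)) { valid$EA <- disc$EA; valid$OA <- disc$OA; return(valid) }
    if (swapped(ea_c, oa_c)) {
      valid$BETA <- -valid$BETA
      if ("EAF" %in% names(valid)) valid$EAF <- 1 - valid$EAF
      valid$EA <- disc$EA; valid$OA <- disc$OA
      return(valid)
    }
  }
  NULL
}

#' Two-stage replication rule
#'
#' A discovery signal replicates when its validation-stage P is below
#' `alpha` (strict) and the validation effect direction matches discovery
#' after allele harmonization. Variants missing from the validation results
#' are reported as not testable.
#'
#' @param discovery,validation Association results with columns `SNP`,
#'   `EA`, `OA`, `BETA`, `P` (discovery rows define the candidates).
#' @param alpha Replication significance level (default 0.05).
#' @return Data.frame per candidate: harmonized validation effect,
#'   `replicated` (logical, NA when not testable) and a `note`.
#' @export
replicate_signals <- function(discovery, validation, alpha = 0.05) {
  .assert(nrow(discovery) >= 1, "no discovery candidates")
  out <- lapply(seq_len(nrow(discovery)), function(i) {
    d <- discovery[i, ]
    j <- match(d$SNP, validation$SNP)
    if (is.na(j)) {
      return(data.frame(SNP = d$SNP, BETA_disc = d$BETA, P_disc = d$P,
                        BETA_valid = NA_real_, P_valid = NA_real_,
                        replicated = NA, note = "missing in validation",
                        stringsAsFactors = FALSE))
    }
    v <- .harmonize_row(d, validation[j, ])
    if (is.null(v)) {
      return(data.frame(SNP = d$SNP, BETA_disc = d$BETA, P_disc = d$P,
                        BETA_valid = NA_real_, P_valid = NA_real_,
                        replicated = NA, note = "allele mismatch",
                        stringsAsFactors = FALSE))
    }
    rep_ok <- (v$P < alpha) && (sign(d$BETA) == sign(v$BETA))
    data.frame(SNP = d$SNP, BETA_disc = d$BETA, P_disc = d$P,
               BETA_valid = v$BETA, P_valid = v$P,
               replicated = rep_ok, note = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Inverse-variance fixed-effect meta-analysis of two stages
#'
#' Weights `w_i = 1 / se_i^2`; combined `beta = sum(w_i beta_i) / sum(w_i)`,
#' `se = sum(w_i)^(-1/2)`, two-sided P from the normal reference for
#' `z = beta / se`. Vectorized over variants.
#'
#' @param beta_1,se_1 Discovery-stage effect and standard error.
#' @param beta_2,se_2 Validation-stage effect and standard error (alleles
#'   harmonized beforehand).
#' @return Data.frame with `BETA_META`, `SE_META`, `Z`, `P_META` plus the
#'   per-stage inputs echoed.
#' @export
#' @examples
#' ivw_meta(-0.38, 0.07, -0.29, 0.14)
ivw_meta <- function(beta_1, se_1, beta_2, se_2) {
  .assert(all(se_1 > 0) && all(se_2 > 0),
          "standard errors must be positive")
  w1 <- 1 / se_1^2
  w2 <- 1 / se_2^2
  beta <- (w1 * beta_1 + w2 * beta_2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  z <- beta / se
  data.frame(BETA_META = beta, SE_META = se, Z = z, P_META = .p_from_z(z),
             BETA_1 = beta_1, SE_1 = se_1, BETA_2 = beta_2, SE_2 = se_2)
}
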