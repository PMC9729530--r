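test_that("LD r2 is the squared dosage correlation, label-invariant", {
  set.seed(51)
  a <- rbinom(200, 2, 0.3)
  expect_equal(ld_r2(a, a), 1.0)
  expect_equal(ld_r2(a, 2 - a), 1.0)
  expect_error(ld_r2(a, rep(1, 200)), "constant")
  b <- rbinom(10000, 2, 0.3)
  c <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(b, c), 0.01)
})

# A deterministic correlated trio plus one distant independent variant.
make_clump_fixture <- function() {
  set.seed(52)
  n <- 400
  base <- rbinom(n, 2, 0.3)
  jitter <- function(g, k) {
    g[sample(n, k)] <- rbinom(k, 2, 0.3)
    g
  }
  D <- cbind(A = base, B = jitter(base, 12), C = jitter(base, 15),
             D = rbinom(n, 2, 0.3))
  stopifnot(ld_r2(D[, "A"], D[, "B"]) > 0.9, ld_r2(D[, "A"], D[, "C"]) > 0.9)
  meta <- data.frame(id = c("A", "B", "C", "D"), chrom = "1",
                     pos = c(1000L, 2000L, 3000L, 5000000L),
                     effect_allele = "A", other_allele = "G")
  list(panel = variant_panel(meta, D),
       results = data.frame(SNP = c("A", "B", "C", "D"), CHR = "1",
                            POS = c(1000L, 2000L, 3000L, 5000000L),
                            P = c(1e-6, 1e-5, 1e-4, 1e-5),
                            stringsAsFactors = FALSE))
}

test_that("greedy clumping absorbs linked neighbours and keeps distant hits", {
  fx <- make_clump_fixture()
  cl <- clump(fx$results, fx$panel)
  expect_identical(cl$index$SNP, c("A", "D"))
  # C at P = 1e-4 is not suggestive, so only A, B, D form clumps
  expect_setequal(cl$membership$SNP, c("A", "B", "D"))
  expect_identical(cl$membership$index_SNP[cl$membership$SNP == "B"], "A")

  # outside the 1 Mb window even perfect LD does not absorb
  meta2 <- data.frame(id = c("x", "y"), chrom = "1",
                      pos = c(1000L, 2001000L),
                      effect_allele = "A", other_allele = "G")
  g <- rbinom(300, 2, 0.4)
  far <- clump(data.frame(SNP = c("x", "y"), CHR = "1",
                          POS = c(1000L, 2001000L), P = c(1e-6, 1e-5)),
               variant_panel(meta2, cbind(x = g, y = g)))
  expect_identical(sort(far$index$SNP), c("x", "y"))

  # nothing suggestive -> empty index set
  none <- clump(transform(fx$results, P = 1e-4), fx$panel)
  expect_equal(nrow(none$index), 0)

  # a suggestive variant missing from the LD panel is an error naming it
  bad <- rbind(fx$results,
               data.frame(SNP = "Z", CHR = "1", POS = 1500L, P = 1e-6))
  expect_error(clump(bad, fx$panel), "Z")
})

test_that("clumping partitions the suggestive set into independent clumps", {
  cfg <- sim_config(n_subjects = 600, variants = default_instruments()[1, ],
                    n_null_variants = 30, ld_block_size = 5,
                    ld_block_r = 0.9, seed = 53)
  panel <- simulate_genotypes(cfg)
  ids <- panel$variants$id[-1]
  set.seed(54)
  res <- data.frame(SNP = ids, CHR = "1",
                    POS = panel$variants$pos[-1],
                    P = 10^-runif(length(ids), 5, 9),
                    stringsAsFactors = FALSE)
  cl <- clump(res, panel)
  expect_setequal(cl$membership$SNP, ids)
  expect_true(all(table(cl$membership$SNP) == 1))
  expect_true(all(cl$membership$index_SNP %in% cl$index$SNP))
  idx <- cl$index
  if (nrow(idx) > 1) {
    for (i in 1:(nrow(idx) - 1)) for (j in (i + 1):nrow(idx)) {
      if (abs(idx$POS[i] - idx$POS[j]) <= 1e6) {
        expect_lt(ld_r2(panel$dosage[, idx$SNP[i]],
                        panel$dosage[, idx$SNP[j]]), 0.5)
      }
    }
  }
})

test_that("replication needs P below alpha and a consistent direction", {
  disc <- data.frame(SNP = "s1", EA = "A", OA = "G", BETA = 0.3, P = 1e-6)
  flip_val <- data.frame(SNP = "s1", EA = "A", OA = "G",
                         BETA = -0.2, P = 0.001)
  expect_false(replicate_signals(disc, flip_val)$replicated)

  border <- transform(flip_val, BETA = 0.2, P = 0.05)
  expect_false(replicate_signals(disc, border)$replicated)  # strict <

  missing_val <- data.frame(SNP = "s2", EA = "A", OA = "G",
                            BETA = 0.2, P = 0.01)
  out <- replicate_signals(disc, missing_val)
  expect_true(is.na(out$replicated))
  expect_match(out$note, "missing")

  # allele-label flip in validation is harmonized away
  ok <- data.frame(SNP = "s1", EA = "A", OA = "G", BETA = 0.25, P = 0.01)
  swapped <- data.frame(SNP = "s1", EA = "G", OA = "A", BETA = -0.25, P = 0.01)
  expect_true(replicate_signals(disc, ok)$replicated)
  expect_identical(replicate_signals(disc, swapped)$replicated,
                   replicate_signals(disc, ok)$replicated)
  expect_equal(replicate_signals(disc, swapped)$BETA_valid, 0.25)
})

test_that("inverse-variance meta-analysis has its closed form and symmetries", {
  eq <- ivw_meta(0.3, 0.1, 0.3, 0.1)
  expect_equal(eq$BETA_META, 0.3)
  expect_equal(eq$SE_META, 0.1 / sqrt(2))

  m <- ivw_meta(-0.38, 0.07, -0.29, 0.14)
  expect_equal(m$BETA_META, -0.362, tolerance = 1e-3)
  expect_equal(m$SE_META, 0.0626099, tolerance = 1e-6)
  expect_equal(m$P_META, 7.389108e-09, tolerance = 1e-5)

  # symmetric in its arguments; equivariant under common rescaling
  s <- ivw_meta(-0.29, 0.14, -0.38, 0.07)
  expect_equal(s$BETA_META, m$BETA_META)
  expect_equal(s$SE_META, m$SE_META)
  r <- ivw_meta(-3.8, 0.7, -2.9, 1.4)
  expect_equal(r$BETA_META, 10 * m$BETA_META)
  expect_equal(r$Z, m$Z)

  # combined estimate between stages, more precise than either
  expect_true(m$BETA_META > -0.38 && m$BETA_META < -0.29)
  expect_lt(m$SE_META, min(0.07, 0.14))
  # dominant-weight limit: huge se on one stage leaves the other
  lim <- ivw_meta(0.5, 0.05, -5, 1e6)
  expect_equal(lim$BETA_META, 0.5, tolerance = 1e-6)
  expect_error(ivw_meta(0.1, 0, 0.1, 0.1), "positive")
})
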