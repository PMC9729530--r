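#' Default pipeline configuration
#'
#' Thresholds default to the study design: genome-wide significance 5e-8,
#' suggestive threshold 5e-5, replication alpha 0.05, QC at MAF 0.05 /
#' HWE P 1e-4 / call rate 0.95, clump window 1 Mb at r^2 0.5. By default
#' the pipeline simulates a discovery cohort of 1,062 and a validation
#' cohort of 227 subjects with the instrument variants of
#' [default_instruments()].
#'
#' @param out_dir Output directory for tables and logs.
#' @param seed Global seed, fanned out to per-stage substreams.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("metabomr_run_"),
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n_discovery = 1062, n_validation = 227,
                    n_null_variants = 200, ld_block_r = 0.8,
                    ld_block_size = 5, theta = 0.3, confounder_effect = 0,
                    variants = NULL),
    inputs = list(discovery = list(genotypes = NULL, variants = NULL,
                                   pheno = NULL),
                  validation = list(genotypes = NULL, variants = NULL,
                                    pheno = NULL)),
    prep = list(covariates = c("age", "sex", "pc1", "pc2"),
                transform = "int", offset = "half"),
    qc = list(maf_min = 0.05, hwe_p_min = 1e-4, call_rate_min = 0.95),
    thresholds = list(genome_wide = 5e-8, suggestive = 5e-5,
                      replication_alpha = 0.05),
    clump = list(window_bp = 1e6, r2_max = 0.5),
    mr = list(outcomes = outcome_traits(), covariates = c("age", "sex"),
              exposure = NULL, wald_method = "delta2")
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_pipeline_config()] entries;
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

.read_genotypes <- function(spec) {
  if (grepl("\\.vcf(\\.gz)?$", spec$genotypes)) {
    read_vcf(spec$genotypes)
  } else {
    read_dosage_tsv(spec$genotypes, spec$variants)
  }
}

#' Run the full two-stage GWAS + one-sample MR pipeline
#'
#' Executes: (optional) cohort simulation -> phenotype preparation ->
#' variant QC -> discovery association scan -> LD clumping of suggestive
#' signals -> validation scan of the index variants -> replication rule ->
#' inverse-variance meta-analysis -> weighted-GRS construction from the
#' replicated discovery effects -> one-sample MR of every configured
#' outcome, plus the instrument pleiotropy check. Every intermediate table
#' is written to `out_dir` as tab-delimited text and each stage appends a
#' structured record (stage, parameters, row counts) to
#' `pipeline_log.jsonl`. Reruns with the same seed produce identical
#' tables.
#'
#' @param config A configuration list (see [default_pipeline_config()]),
#'   or a path to a YAML file.
#' @return Object of class `pipeline_report`: the per-stage tables, the
#'   genomic inflation factor, the `mr_result`, and the written file paths.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  write_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- list(log = log_path)

  # ---- inputs: simulate or read ----------------------------------------
  cohorts <- run_stage("inputs", {
    if (isTRUE(cfg$simulate$enabled)) {
      sv <- cfg$simulate$variants
      sv <- if (is.null(sv)) default_instruments() else as.data.frame(sv)
      mk <- function(n, seed) {
        sc <- sim_config(
          n_subjects = n, variants = sv,
          n_null_variants = cfg$simulate$n_null_variants,
          ld_block_r = cfg$simulate$ld_block_r,
          ld_block_size = cfg$simulate$ld_block_size,
          theta = cfg$simulate$theta,
          confounder_effect = cfg$simulate$confounder_effect,
          seed = seed)
        simulate_cohort(sc)
      }
      d <- mk(cfg$simulate$n_discovery, cfg$seed)
      v <- mk(cfg$simulate$n_validation, cfg$seed + 1000L)
      log_stage("simulate", n_discovery = cfg$simulate$n_discovery,
                n_validation = cfg$simulate$n_validation,
                n_variants = ncol(d$panel$dosage), seed = cfg$seed)
      list(discovery = d, validation = v)
    } else {
      rd <- function(spec, label) {
        panel <- .read_genotypes(spec)
        pheno <- read_pheno(spec$pheno,
                            required = c(cfg$prep$covariates, "metabolite"))
        al <- align_cohort(panel, pheno)
        log_stage("read_inputs", cohort = label,
                  n_subjects = length(al$panel$subjects),
                  n_variants = ncol(al$panel$dosage))
        al
      }
      list(discovery = rd(cfg$inputs$discovery, "discovery"),
           validation = rd(cfg$inputs$validation, "validation"))
    }
  })

  # ---- phenotype preparation -------------------------------------------
  prep_one <- function(pheno) {
    covs <- intersect(cfg$prep$covariates, names(pheno))
    prepare_trait(pheno$metabolite,
                  if (length(covs)) pheno[covs] else NULL,
                  transform = cfg$prep$transform, offset = cfg$prep$offset)
  }
  y_d <- run_stage("prep", prep_one(cohorts$discovery$pheno))
  y_v <- run_stage("prep", prep_one(cohorts$validation$pheno))
  log_stage("prep", transform = cfg$prep$transform,
            covariates = attr(y_d, "prep")$covariates)

  # ---- variant QC + discovery scan -------------------------------------
  qc_d <- run_stage("qc", filter_variants(
    cohorts$discovery$panel, cfg$qc$maf_min, cfg$qc$hwe_p_min,
    cfg$qc$call_rate_min))
  files$qc_log <- write_tsv(qc_d$log, "qc_discovery.tsv")
  log_stage("qc", cohort = "discovery", n_in = nrow(qc_d$log),
            n_kept = sum(qc_d$log$kept))

  res_d <- run_stage("gwas_discovery", assoc_scan(qc_d$panel, y_d))
  lambda <- genomic_inflation(statistic = res_d$STAT^2)
  files$gwas_discovery <- write_tsv(res_d, "gwas_discovery.tsv")
  files$qq <- write_tsv(qq_data(res_d), "qq_discovery.tsv")
  files$manhattan <- write_tsv(manhattan_data(res_d), "manhattan_discovery.tsv")
  log_stage("gwas", cohort = "discovery", n_variants = nrow(res_d),
            lambda = lambda,
            n_genome_wide = sum(res_d$P < cfg$thresholds$genome_wide),
            n_suggestive = sum(res_d$P < cfg$thresholds$suggestive))

  # ---- clump -> validate -> replicate -> meta --------------------------
  cl <- run_stage("clump", clump(res_d, qc_d$panel,
                                 window_bp = cfg$clump$window_bp,
                                 r2_max = cfg$clump$r2_max,
                                 p_suggestive = cfg$thresholds$suggestive))
  files$clump <- write_tsv(cl$membership, "clump_membership.tsv")
  files$clump_index <- write_tsv(cl$index, "clump_index.tsv")
  log_stage("clump", n_suggestive = nrow(cl$membership),
            n_index = nrow(cl$index))

  empty_report <- function(msg) {
    warning(msg)
    structure(list(config = cfg, lambda = lambda,
                   gwas_discovery = res_d, clump = cl,
                   gwas_validation = NULL, replication = NULL, meta = NULL,
                   weights = NULL, mr = NULL, pleiotropy = NULL,
                   files = files),
              class = "pipeline_report")
  }
  if (nrow(cl$index) == 0) {
    log_stage("done", status = "no suggestive signals")
    return(empty_report("no suggestive signals; downstream stages skipped"))
  }

  idx_ids <- cl$index$SNP
  testable <- intersect(idx_ids, cohorts$validation$panel$variants$id)
  res_v <- run_stage("gwas_validation", assoc_scan(
    subset_panel(cohorts$validation$panel, testable), y_v))
  files$gwas_validation <- write_tsv(res_v, "gwas_validation.tsv")
  log_stage("gwas", cohort = "validation", n_variants = nrow(res_v))

  rep_tab <- run_stage("replicate", replicate_signals(
    cl$index, res_v, alpha = cfg$thresholds$replication_alpha))
  files$replication <- write_tsv(rep_tab, "replication.tsv")
  log_stage("replicate", n_candidates = nrow(rep_tab),
            n_replicated = sum(rep_tab$replicated, na.rm = TRUE))

  rep_ok <- rep_tab[!is.na(rep_tab$replicated) & rep_tab$replicated, ]
  if (nrow(rep_ok) == 0) {
    log_stage("done", status = "no replicated signals")
    return(empty_report("no replicated signals; meta-analysis and MR skipped"))
  }

  meta_tab <- run_stage("meta", {
    m <- ivw_meta(rep_ok$BETA_disc,
                  cl$index$SE[match(rep_ok$SNP, cl$index$SNP)],
                  rep_ok$BETA_valid,
                  res_v$SE[match(rep_ok$SNP, res_v$SNP)])
    cbind(SNP = rep_ok$SNP, m)
  })
  files$meta <- write_tsv(meta_tab, "meta.tsv")
  log_stage("meta", n_variants = nrow(meta_tab))

  # ---- instrument + one-sample MR --------------------------------------
  disc_rows <- cl$index[match(rep_ok$SNP, cl$index$SNP), ]
  weights <- orient_weights(data.frame(
    SNP = disc_rows$SNP, EA = disc_rows$EA, OA = disc_rows$OA,
    BETA = disc_rows$BETA, stringsAsFactors = FALSE))
  files$weights <- write_tsv(weights, "grs_weights.tsv")

  mr_fit <- run_stage("mr", run_mr(
    cohorts$discovery$panel, cohorts$discovery$pheno, weights,
    outcomes = intersect(cfg$mr$outcomes, names(cohorts$discovery$pheno)),
    exposure = if (is.null(cfg$mr$exposure)) y_d else cfg$mr$exposure,
    covariates = cfg$mr$covariates, wald_method = cfg$mr$wald_method))
  files$mr <- write_tsv(mr_fit$table, "mr_report.tsv")
  log_stage("mr", n_instruments = nrow(weights),
            F = mr_fit$first_stage$F, n = mr_fit$first_stage$n)

  pleio <- run_stage("pleiotropy", pleiotropy_check(
    mr_fit$score,
    cohorts$discovery$pheno[intersect(cfg$mr$covariates,
                                      names(cohorts$discovery$pheno))]))
  files$pleiotropy <- write_tsv(pleio, "pleiotropy_check.tsv")
  log_stage("done", status = "complete")

  structure(list(config = cfg, lambda = lambda, gwas_discovery = res_d,
                 clump = cl, gwas_validation = res_v, replication = rep_tab,
                 meta = meta_tab, weights = weights, mr = mr_fit,
                 pleiotropy = pleio, files = files),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Two-stage GWAS + one-sample MR pipeline report\n")
  cat(sprintf("  discovery scan: %d variants, lambda = %.3f\n",
              nrow(x$gwas_discovery), x$lambda))
  cat(sprintf("  clump indices: %d\n", nrow(x$clump$index)))
  if (!is.null(x$replication)) {
    cat(sprintf("  replicated: %d of %d\n",
                sum(x$replication$replicated, na.rm = TRUE),
                nrow(x$replication)))
  }
  if (!is.null(x$mr)) {
    cat(sprintf("  instrument F = %.2f; %d outcome(s) analysed\n",
                x$mr$first_stage$F, nrow(x$mr$table)))
  }
  cat("  outputs: ", dirname(x$files$log), "\n", sep = "")
  invisible(x)
}
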