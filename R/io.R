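# File interfaces: VCF 4.2 (GT hard calls), tab-delimited dosage matrices,
# phenotype tables, and the simulated-cohort bundle with its ground-truth
# JSON sidecar.

#' Write a variant panel as VCF 4.2
#'
#' One record per variant; the effect allele is written as ALT and the
#' other allele as REF, with hard-call GT genotypes (rounded dosages) and
#' `./.` for masked entries.
#'
#' @param panel A [variant_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    g <- round(panel$dosage[, j])
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$subjects), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF into a variant panel
#'
#' Uses the GT field (hard calls; ALT-allele dosage 0/1/2) or, when GT is
#' absent, the DS dosage field. The effect allele is ALT. Missing genotypes
#' (`./.`) are masked.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A [variant_panel()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  .assert(nrow(fix) >= 1, "VCF contains no variant records")
  fmt <- strsplit(unname(vcf@gt[1, "FORMAT"]), ":")[[1]]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         effect_allele = fix$ALT, other_allele = fix$REF,
                         stringsAsFactors = FALSE)
  if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alleles <- strsplit(as.vector(gt), "[/|]")
    dos <- vapply(alleles, function(a) {
      if (length(a) == 0 || any(is.na(a)) || any(a == ".")) NA_real_
      else sum(a == "1")
    }, numeric(1))
    dosage <- matrix(dos, nrow = nrow(gt))
  } else if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    dosage <- matrix(as.numeric(ds), nrow = nrow(ds))
  } else {
    stop("VCF has neither GT nor DS in FORMAT", call. = FALSE)
  }
  # vcfR matrices are variants x subjects; the panel is subjects x variants
  subjects <- colnames(vcf@gt)[-1]
  variant_panel(variants, t(dosage), subjects = subjects)
}

#' Write a dosage matrix and variant metadata as tab-delimited text
#'
#' @param panel A [variant_panel()].
#' @param dosage_path Output path for the subjects-by-variants dosage
#'   matrix (first column `subject_id`, then one column per variant id).
#' @param variants_path Optional path for the variant metadata table.
#' @return `dosage_path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, dosage_path, variants_path = NULL) {
  df <- data.frame(subject_id = panel$subjects,
                   as.data.frame(panel$dosage, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, dosage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(variants_path)) {
    utils::write.table(panel$variants, variants_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dosage_path)
}

#' Read a tab-delimited dosage matrix into a variant panel
#'
#' @param dosage_path Dosage matrix written by [write_dosage_tsv()].
#' @param variants_path Optional variant metadata table; when absent,
#'   chromosome/position/alleles are NA.
#' @return A [variant_panel()].
#' @export
read_dosage_tsv <- function(dosage_path, variants_path = NULL) {
  df <- utils::read.delim(dosage_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  .assert("subject_id" %in% names(df),
          "dosage table must have a subject_id column")
  subjects <- as.character(df$subject_id)
  dosage <- as.matrix(df[setdiff(names(df), "subject_id")])
  variants <- if (!is.null(variants_path)) {
    utils::read.delim(variants_path, stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
  } else {
    data.frame(id = colnames(dosage), chrom = NA_character_,
               pos = NA_integer_, effect_allele = NA_character_,
               other_allele = NA_character_, stringsAsFactors = FALSE)
  }
  idx <- match(colnames(dosage), variants$id)
  .assert(!anyNA(idx), "variant metadata does not cover all dosage columns")
  variant_panel(variants[idx, , drop = FALSE], dosage, subjects = subjects)
}

#' Read a phenotype table
#'
#' @param path Tab-delimited phenotype table with a `subject_id` column.
#' @param required Optional column names that must be present; a missing
#'   column raises an error naming it.
#' @return Data.frame of class `pheno_table`.
#' @export
read_pheno <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert("subject_id" %in% names(df),
          "phenotype table must have a subject_id column")
  df$subject_id <- as.character(df$subject_id)
  missing_cols <- setdiff(required, names(df))
  .assert(length(missing_cols) == 0,
          paste("phenotype table lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Write a phenotype table
#' @param pheno Phenotype data.frame with `subject_id`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_pheno <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort bundle
#'
#' Writes the genotypes as VCF and as a dosage matrix, the variant
#' metadata, the phenotype table, and a ground-truth JSON (configuration
#' echo plus realized allele frequencies) under a common path prefix.
#'
#' @param panel A [variant_panel()].
#' @param pheno The matching phenotype table.
#' @param prefix Output path prefix.
#' @return Named list of the written file paths.
#' @export
write_cohort <- function(panel, pheno, prefix) {
  paths <- list(vcf = paste0(prefix, ".vcf"),
                dosage = paste0(prefix, ".dosage.tsv"),
                variants = paste0(prefix, ".variants.tsv"),
                pheno = paste0(prefix, ".pheno.tsv"),
                truth = paste0(prefix, ".truth.json"))
  write_vcf(panel, paths$vcf)
  write_dosage_tsv(panel, paths$dosage, paths$variants)
  write_pheno(pheno, paths$pheno)
  truth <- attr(pheno, "truth")
  echo <- if (!is.null(truth)) {
    cfg <- truth$config
    list(config = c(unclass(cfg)[setdiff(names(cfg), "variants")],
                    list(variants = cfg$variants)),
         beta_metabolite = as.list(truth$beta_metabolite),
         theta = as.list(truth$theta),
         realized_eaf = as.list(round(colMeans(panel$dosage,
                                               na.rm = TRUE) / 2, 6)))
  } else {
    list(realized_eaf = as.list(round(colMeans(panel$dosage,
                                               na.rm = TRUE) / 2, 6)))
  }
  jsonlite::write_json(echo, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Align a genotype panel and phenotype table by subject id
#'
#' Intersects subject ids, keeps the common subjects in panel order, and
#' reports the overlap.
#'
#' @param panel A [variant_panel()].
#' @param pheno A phenotype table with `subject_id`.
#' @return List with aligned `panel` and `pheno`.
#' @export
align_cohort <- function(panel, pheno) {
  common <- intersect(panel$subjects, pheno$subject_id)
  .assert(length(common) > 0, "no overlapping subjects between files")
  keep <- panel$subjects %in% common
  panel2 <- variant_panel(panel$variants,
                          panel$dosage[keep, , drop = FALSE],
                          subjects = panel$subjects[keep])
  pheno2 <- pheno[match(panel2$subjects, pheno$subject_id), , drop = FALSE]
  rownames(pheno2) <- NULL
  message(sprintf("aligned %d of %d genotyped / %d phenotyped subjects",
                  length(common), length(panel$subjects), nrow(pheno)))
  list(panel = panel2, pheno = pheno2)
}
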