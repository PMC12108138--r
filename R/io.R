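.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read and write phenotype tables
#'
#' Tab-delimited with header `sample_id, height_cm, sex, age_years,
#' weight_kg, bmi, sbp, dbp, antihtn`.
#'
#' @param ph Phenotype table.
#' @param path File path.
#' @return `read_phenotypes` returns a `phenotype_table` data frame.
#' @export
write_phenotypes <- function(ph, path) .write_tsv(ph, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- .read_tsv(path)
  if (!"sample_id" %in% names(ph)) stop("phenotype file lacks 'sample_id'", call. = FALSE)
  if ("sex" %in% names(ph)) ph$sex <- factor(ph$sex, levels = c("female", "male"))
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Write genotypes as a dosage matrix plus variant side-car
#'
#' Produces `<prefix>.dosage.tsv` (variants x samples, first column
#' `variant_id`, then one column per sample; missing as `NA`) and
#' `<prefix>.variants.tsv` (id, chrom, pos, effect_allele, other_allele,
#' info).
#'
#' @param g A [genotype_matrix()].
#' @param prefix Path prefix for the two files.
#' @return The two paths, invisibly.
#' @export
write_dosage_tsv <- function(g, prefix) {
  d <- t(g$dosage)
  df <- data.frame(variant_id = g$variants$id, d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  p1 <- paste0(prefix, ".dosage.tsv")
  p2 <- paste0(prefix, ".variants.tsv")
  .write_tsv(df, p1)
  .write_tsv(g$variants, p2)
  invisible(c(p1, p2))
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(prefix) {
  p1 <- paste0(prefix, ".dosage.tsv")
  p2 <- paste0(prefix, ".variants.tsv")
  if (!file.exists(p1) || !file.exists(p2))
    stop("dosage or variant file missing for prefix '", prefix, "'", call. = FALSE)
  df <- .read_tsv(p1)
  v <- .read_tsv(p2)
  v$chrom <- as.character(v$chrom)
  d <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(d) <- "double"
  colnames(d) <- df$variant_id
  if (!identical(as.character(df$variant_id), as.character(v$id)))
    stop("variant order differs between dosage and metadata files", call. = FALSE)
  genotype_matrix(d, v)
}

#' Write genotypes to VCF
#'
#' VCF 4.2 with the per-variant imputation score in an `INFO=` key and
#' dosages in a `DS` FORMAT field (missing as `.`).
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the alternate (effect) allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosage)), collapse = "\t")),
             con)
  ds <- t(g$dosage)
  ds_chr <- matrix(ifelse(is.na(ds), ".", format(ds, trim = TRUE, digits = 6)),
                   nrow = nrow(ds))
  v <- g$variants
  lines <- paste(v$chrom, v$pos, v$id, v$other_allele, v$effect_allele, ".",
                 "PASS", sprintf("INFO=%g", v$info), "DS",
                 apply(ds_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Reads dosages from the `DS` FORMAT field (falling back to counting
#' alternate alleles in `GT` when `DS` is absent) and the imputation
#' score from the `INFO=` key (1 when absent, i.e. directly genotyped).
#' The ALT allele is taken as the effect allele.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      out <- rep(NA_real_, length(col))
      known <- !is.na(col) & !grepl("\\.", col)
      out[known] <- vapply(strsplit(col[known], "[/|]"),
                           function(a) sum(a == "1"), numeric(1))
      out
    })
  }
  info <- suppressWarnings(as.numeric(vcfR::extract.info(v, "INFO")))
  info[is.na(info)] <- 1
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- sprintf("var%06d", which(is.na(ids) | ids == "."))
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         effect_allele = fix$ALT, other_allele = fix$REF,
                         info = info, stringsAsFactors = FALSE)
  d <- t(ds)
  colnames(d) <- variants$id
  genotype_matrix(d, variants)
}

#' Read genotypes from VCF or dosage TSV
#'
#' @param path A `.vcf`/`.vcf.gz` file, or the prefix of a
#'   `.dosage.tsv`/`.variants.tsv` pair.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    read_vcf(path)
  } else {
    read_dosage_tsv(sub("\\.dosage\\.tsv$", "", path))
  }
}

#' Read and write GWAS summary statistics
#'
#' Tab-delimited with the GWAS-SSF-style columns produced by
#' [gwas_scan()].
#'
#' @param ss A `summary_stats` data frame.
#' @param path File path.
#' @export
write_summary_stats <- function(ss, path) .write_tsv(ss, path)

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  ss <- .read_tsv(path)
  ss$chromosome <- as.character(ss$chromosome)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

#' Read and write PRS model files
#'
#' Tab-delimited `variant_id, chrom, pos, effect_allele, weight,
#' p_source`; the p-threshold and source label travel in `#`-prefixed
#' header comments.
#'
#' @param model A [prs_model()].
#' @param path File path.
#' @export
write_prs_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#p_threshold=%s", model$p_threshold),
               sprintf("#source=%s", model$source)), con)
  utils::write.table(model$entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_prs_model
#' @export
read_prs_model <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  thr <- sub("^#p_threshold=", "", meta[startsWith(meta, "#p_threshold=")])
  src <- sub("^#source=", "", meta[startsWith(meta, "#source=")])
  entries <- utils::read.table(path, sep = "\t", header = TRUE,
                               comment.char = "#", stringsAsFactors = FALSE)
  entries$chrom <- as.character(entries$chrom)
  prs_model(entries,
            p_threshold = suppressWarnings(as.numeric(thr)),
            source = if (length(src)) src else "unknown")
}

#' Write a PRS profile (score file)
#'
#' @param profile A `prs_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) .write_tsv(profile, path)

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one object that round-trips
#' losslessly through YAML.
#'
#' @param n_samples,n_blocks,block_size,within_block_rho,n_subpops,fst
#'   Synthetic-cohort layout (used when `simulate = TRUE`).
#' @param n_causal,heritability,secondary_rho Trait architecture.
#' @param missing_rate,bad_sample_fraction Degradation settings.
#' @param simulate Generate the cohort (`TRUE`) or read it from
#'   `genotype_path`/`phenotype_path`.
#' @param genotype_path,phenotype_path Input paths when `simulate = FALSE`.
#' @param trait,covariates Analysis columns.
#' @param n_iterations,split,min_freq Ensemble settings.
#' @param qc,prune,ct Parameter objects (stored as plain lists in YAML).
#' @param alpha,max_pc Tracy-Widom settings.
#' @param holdout_fraction,holdout_repeats Validation settings.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 600, n_blocks = 40, block_size = 50,
                            within_block_rho = 0.7, n_subpops = 1, fst = 0,
                            n_causal = 100, heritability = 0.5,
                            secondary_rho = 0.3, missing_rate = 0.02,
                            bad_sample_fraction = 0, simulate = TRUE,
                            genotype_path = NULL, phenotype_path = NULL,
                            trait = "height_cm",
                            covariates = c("sex", "age_years"),
                            n_iterations = 10, split = 0.8,
                            min_freq = ceiling(0.1 * n_iterations),
                            qc = qc_thresholds(), prune = prune_params(),
                            ct = ct_params(), alpha = 0.05, max_pc = 20,
                            holdout_fraction = 0.2, holdout_repeats = 20,
                            seed = 1) {
  cfg <- list(n_samples = n_samples, n_blocks = n_blocks,
              block_size = block_size, within_block_rho = within_block_rho,
              n_subpops = n_subpops, fst = fst, n_causal = n_causal,
              heritability = heritability, secondary_rho = secondary_rho,
              missing_rate = missing_rate,
              bad_sample_fraction = bad_sample_fraction,
              simulate = simulate, genotype_path = genotype_path,
              phenotype_path = phenotype_path, trait = trait,
              covariates = covariates, n_iterations = n_iterations,
              split = split, min_freq = min_freq,
              qc = unclass(qc), prune = unclass(prune), ct = unclass(ct),
              alpha = alpha, max_pc = max_pc,
              holdout_fraction = holdout_fraction,
              holdout_repeats = holdout_repeats, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$qc <- do.call(qc_thresholds, cfg$qc)
  cfg$prune <- do.call(prune_params, cfg$prune)
  cfg$ct <- do.call(ct_params, cfg$ct)
  cfg2 <- do.call(pipeline_config, cfg)
  cfg2
}

#' Run the whole pipeline end to end
#'
#' Simulates (or reads) a cohort, fits the stability-selected PRS,
#' validates it on hold-outs, associates it with the secondary
#' phenotype, and writes every artifact plus a manifest with MD5 content
#' hashes and a run log to `run_dir`. Outputs contain no timestamps, so
#' a repeated run with the same configuration produces hash-identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @param run_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted `prs_stability` object, the
#'   validation result, the secondary-association table and the manifest.
#' @export
full_run <- function(config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(run_dir, name)
    writer(obj, p)
    paths <<- c(paths, p)
    p
  }
  log_lines <- c(sprintf("stabprs full_run"),
                 sprintf("seed: %d", config$seed),
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("stabprs"))))
  stage <- "input"
  status <- list()
  result <- tryCatch({
    if (isTRUE(config$simulate)) {
      cohort <- simulate_cohort(
        n_samples = config$n_samples,
        ld = ld_block_spec(config$n_blocks, config$block_size,
                           config$within_block_rho),
        structure = structure_spec(config$n_subpops, config$fst),
        arch = trait_architecture(n_causal = config$n_causal,
                                  heritability = config$heritability),
        secondary_rho = config$secondary_rho,
        missing_rate = config$missing_rate,
        bad_sample_fraction = config$bad_sample_fraction,
        seed = config$seed)
      g <- cohort$genotypes
      ph <- cohort$phenotypes
      paths <- c(paths, write_dosage_tsv(g, file.path(run_dir, "cohort")))
      emit(write_phenotypes, ph, "phenotypes.tsv")
    } else {
      g <- read_genotypes(config$genotype_path)
      ph <- read_phenotypes(config$phenotype_path)
    }
    status[["input"]] <- "ok"

    stage <- "fit"
    fit <- prs_stability(g, ph, trait = config$trait,
                         covariates = config$covariates,
                         n_iterations = config$n_iterations,
                         split = config$split, min_freq = config$min_freq,
                         qc = do.call(qc_thresholds, config$qc),
                         prune = do.call(prune_params, config$prune),
                         ct = do.call(ct_params, config$ct),
                         alpha = config$alpha,
                         max_pc = config$max_pc, seed = config$seed)
    status[["fit"]] <- "ok"
    emit(write_summary_stats, fit$whole_ss, "summary_stats.tsv")
    emit(write_prs_model, fit$final_model, "final_prs.tsv")
    emit(write_profile, fit$profile, "scores.tsv")
    emit(.write_tsv, fit$candidates$table, "candidates.tsv")
    emit(.write_tsv, data.frame(variant_id = names(fit$freq_table),
                                count = as.integer(fit$freq_table)),
         "frequency_table.tsv")
    emit(.write_tsv,
         data.frame(iteration = vapply(fit$ensemble$records, `[[`,
                                       numeric(1), "iteration"),
                    incremental_r2 = fit$ensemble$baseline_r2,
                    empirical_p = vapply(fit$ensemble$records, `[[`,
                                         numeric(1), "empirical_p"),
                    n_snps = vapply(fit$ensemble$records,
                                    function(r) r$model$n_snps, numeric(1))),
         "iterations.tsv")

    stage <- "validate"
    val <- holdout_validate(fit$final_model, fit$genotypes, fit$phenotypes,
                            fraction = config$holdout_fraction,
                            repeats = config$holdout_repeats,
                            trait = config$trait,
                            covariates = config$covariates, pcs = fit$pca,
                            seed = config$seed)
    status[["validate"]] <- "ok"
    emit(.write_tsv,
         data.frame(metric = c("mean_r2", "sd_r2", "mean_incremental_r2",
                               "sd_incremental_r2", "mean_pearson_r",
                               "mean_scaled_beta", "median_beta_p"),
                    value = c(val$mean_r2, val$sd_r2,
                              val$mean_incremental_r2,
                              val$sd_incremental_r2, val$mean_r,
                              val$mean_beta, val$median_beta_p)),
         "validation.tsv")

    stage <- "secondary"
    sec <- secondary_association(fit$profile, fit$phenotypes)
    status[["secondary"]] <- "ok"
    emit(.write_tsv, sec, "secondary_association.tsv")
    list(fit = fit, validation = val, secondary = sec)
  }, error = function(e) {
    status[[stage]] <<- paste("failed:", conditionMessage(e))
    e
  })
  log_lines <- c(log_lines,
                 vapply(names(status), function(s)
                   sprintf("stage %s: %s", s, status[[s]]), character(1)))
  writeLines(log_lines, file.path(run_dir, "run_log.txt"))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(run_dir, "manifest.tsv"))
  if (inherits(result, "error"))
    stop("full_run failed at stage '", stage, "': ",
         conditionMessage(result), call. = FALSE)
  invisible(c(result, list(manifest = manifest)))
}
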