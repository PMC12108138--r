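.qc_report <- function(axis, n_in, steps) {
  removed <- vapply(steps, `[[`, numeric(1), "n_removed")
  data.frame(axis = axis,
             step = vapply(steps, `[[`, character(1), "step"),
             threshold = vapply(steps, `[[`, numeric(1), "threshold"),
             n_in = n_in - c(0, cumsum(removed))[seq_along(steps)],
             n_removed = removed,
             n_out = n_in - cumsum(removed),
             stringsAsFactors = FALSE)
}

#' Variant-level quality control
#'
#' Removes variants whose imputation INFO score, call rate or folded
#' minor-allele frequency (computed on non-missing dosages) is strictly
#' below the corresponding threshold. Filters are applied sequentially in
#' the order INFO, call rate, MAF, and the report counts removals per
#' rule in that order. Variants with a missing INFO value are treated as
#' directly genotyped (INFO = 1) with a warning. Monomorphic variants
#' fall to the MAF rule.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `genotypes` (filtered matrix) and `report`
#'   (data frame of per-rule counts, class `qc_report`).
#' @export
filter_variants <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  info <- g$variants$info
  if (anyNA(info)) {
    warning(sum(is.na(info)),
            " variant(s) lack an INFO value; treated as directly genotyped (INFO = 1)")
    info[is.na(info)] <- 1
  }
  n_in <- ncol(g$dosage)
  st <- .col_stats_cpp(g$dosage)
  maf <- pmin(st$mean / 2, 1 - st$mean / 2)
  maf[is.na(maf)] <- 0  # all-missing columns
  keep1 <- info >= thresholds$min_info
  keep2 <- keep1 & st$callrate >= thresholds$min_variant_callrate
  keep3 <- keep2 & maf >= thresholds$min_maf
  if (!any(keep3))
    stop("no variants survive QC", call. = FALSE)
  g3 <- subset_genotypes(g, variants = keep3)
  report <- .qc_report("variant", n_in, list(
    list(step = "info", threshold = thresholds$min_info,
         n_removed = sum(!keep1)),
    list(step = "callrate", threshold = thresholds$min_variant_callrate,
         n_removed = sum(keep1) - sum(keep2)),
    list(step = "maf", threshold = thresholds$min_maf,
         n_removed = sum(keep2) - sum(keep3))))
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = g3, report = report)
}

#' Sample-level quality control
#'
#' Removes samples whose call rate over the current (post variant-filter)
#' variants is strictly below `min_sample_callrate`.
#'
#' @inheritParams filter_variants
#' @return A list with `genotypes` and `report` as in [filter_variants()].
#' @export
filter_samples <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (ncol(g$dosage) < 1) stop("at least one variant required", call. = FALSE)
  n_in <- nrow(g$dosage)
  keep <- sample_callrate(g) >= thresholds$min_sample_callrate
  if (!any(keep)) stop("no samples survive QC", call. = FALSE)
  out <- subset_genotypes(g, samples = keep)
  report <- .qc_report("sample", n_in, list(
    list(step = "callrate", threshold = thresholds$min_sample_callrate,
         n_removed = sum(!keep))))
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = out, report = report)
}

#' Greedy windowed LD pruning
#'
#' Scans variants per chromosome in position order and keeps a variant
#' only if its squared correlation with every already-kept variant within
#' `window_kb` kilobases is at most `r2_threshold`; the earlier variant
#' of a correlated pair therefore survives. Correlations are computed on
#' mean-imputed, standardized dosages. The returned set never contains a
#' within-window pair above the threshold.
#'
#' @param g A [genotype_matrix()].
#' @param params A [prune_params()].
#' @return Character vector of retained variant ids, in genomic order.
#' @export
ld_prune <- function(g, params = prune_params()) {
  stopifnot(inherits(params, "prune_params"))
  v <- g$variants
  if (anyNA(v$pos) || anyNA(v$chrom))
    stop("variants must carry chromosome and position for pruning", call. = FALSE)
  chrf <- factor(v$chrom, levels = unique(v$chrom))
  ord <- order(as.integer(chrf), v$pos)
  Z <- standardize_dosage(g, "unit")[, ord, drop = FALSE]
  keep <- .prune_cpp(Z, as.numeric(v$pos[ord]), as.integer(chrf)[ord],
                     params$window_kb * 1000, params$r2_threshold)
  v$id[ord][keep]
}
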