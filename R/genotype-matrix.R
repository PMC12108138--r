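#' Genotype dosage matrix with per-variant metadata
#'
#' The central genotype container: a samples x variants matrix of
#' effect-allele dosages (0, 1, 2 for hard calls; fractional values are
#' allowed for imputed data) with `NA` marking missing genotypes, plus a
#' per-variant metadata table. Missing genotypes are always encoded as
#' `NA`, never as 0.
#'
#' @param dosage Numeric matrix, samples in rows and variants in columns.
#'   Row and column names are used as sample and variant identifiers.
#' @param variants Data frame with one row per variant and columns
#'   `id`, `chrom`, `pos` (1-based), `effect_allele`, `other_allele`,
#'   `info` (imputation quality in `[0, 1]`; `1` for directly genotyped
#'   variants).
#' @return An object of class `genotype_matrix` with elements `dosage`
#'   and `variants`.
#' @export
genotype_matrix <- function(dosage, variants) {
  if (!is.matrix(dosage) || !is.numeric(dosage))
    stop("'dosage' must be a numeric matrix", call. = FALSE)
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele", "info")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("'variants' lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(variants) != ncol(dosage))
    stop("'variants' must have one row per dosage column", call. = FALSE)
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique", call. = FALSE)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("sample%04d", seq_len(nrow(dosage)))
  colnames(dosage) <- variants$id
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  variants <- as.data.frame(variants)[, need]
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  nm <- sum(is.na(d))
  cat(sprintf("genotype_matrix: %d samples x %d variants (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * nm / length(d)))
  cat(sprintf("  chrom: %s; INFO in [%.2f, %.2f]\n",
              paste(unique(x$variants$chrom), collapse = ","),
              min(x$variants$info), max(x$variants$info)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample and variant identifiers of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' @rdname sample_ids
#' @export
variant_ids <- function(g) g$variants$id

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples,variants Identifiers (character), indices, or a logical
#'   mask selecting rows/columns to keep; `NULL` keeps all.
#' @return A new `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  d <- g$dosage
  v <- g$variants
  if (!is.null(variants)) {
    idx <- if (is.character(variants)) match(variants, v$id) else which(rep(TRUE, nrow(v)))[variants]
    if (anyNA(idx)) stop("unknown variant id(s)", call. = FALSE)
    d <- d[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
  }
  sp <- attr(g, "subpop")
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, rownames(d)) else seq_len(nrow(d))[samples]
    if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
    d <- d[idx, , drop = FALSE]
    if (!is.null(sp)) sp <- sp[idx]
  }
  .gm(d, v, sp)
}

#' Per-variant and per-sample summaries
#'
#' `variant_callrate()` and `sample_callrate()` are fractions of
#' non-missing genotypes; `variant_freq()` is the effect-allele frequency
#' computed on non-missing dosages; `variant_maf()` folds it to `<= 0.5`.
#'
#' @param g A [genotype_matrix()].
#' @return A named numeric vector.
#' @export
variant_callrate <- function(g)
  stats::setNames(.col_stats_cpp(g$dosage)$callrate, colnames(g$dosage))

#' @rdname variant_callrate
#' @export
sample_callrate <- function(g)
  stats::setNames(.row_callrate_cpp(g$dosage), rownames(g$dosage))

#' @rdname variant_callrate
#' @export
variant_freq <- function(g)
  stats::setNames(.col_stats_cpp(g$dosage)$mean / 2, colnames(g$dosage))

#' @rdname variant_callrate
#' @export
variant_maf <- function(g) {
  p <- variant_freq(g)
  pmin(p, 1 - p)
}

#' Mean-imputed, standardized dosage matrix
#'
#' Missing dosages are replaced by the variant mean (2 p-hat). With
#' `scale = "unit"` each column is centred and divided by its sample
#' standard deviation; with `scale = "patterson"` columns are centred at
#' `2 p-hat` and divided by `sqrt(2 p-hat (1 - p-hat))`, the scaling
#' conventionally used before genotype PCA. Columns with zero variance
#' come back as all zeros.
#'
#' @param g A [genotype_matrix()].
#' @param scale `"unit"` or `"patterson"`.
#' @return A numeric matrix of the same dimension as `g$dosage`.
#' @export
standardize_dosage <- function(g, scale = c("unit", "patterson")) {
  scale <- match.arg(scale)
  Z <- .standardize_cpp(g$dosage, scale == "patterson")
  dimnames(Z) <- dimnames(g$dosage)
  Z
}

# internal constructor bypassing validation for subsets of already
# validated objects
.gm <- function(dosage, variants, subpop = NULL) {
  out <- structure(list(dosage = dosage, variants = variants),
                   class = "genotype_matrix")
  if (!is.null(subpop)) attr(out, "subpop") <- subpop
  out
}
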