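.covariate_matrix <- function(ph, covariates, pcs = NULL, samples = NULL) {
  if (is.null(samples)) samples <- ph$sample_id
  rows <- match(samples, ph$sample_id)
  if (anyNA(rows)) stop("sample(s) absent from the phenotype table", call. = FALSE)
  sub <- ph[rows, , drop = FALSE]
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(sub)) stop("covariate '", cv, "' not found", call. = FALSE)
    x <- sub[[cv]]
    if (is.factor(x)) as.numeric(x) - 1 else as.numeric(x)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  if (!is.null(pcs)) {
    P <- if (inherits(pcs, "pca_basis")) pc_covariates(pcs, samples) else {
      idx <- match(samples, rownames(pcs))
      if (anyNA(idx)) stop("sample(s) absent from PC loadings", call. = FALSE)
      pcs[idx, , drop = FALSE]
    }
    if (ncol(P) > 0) X <- cbind(X, P)
  }
  cbind(`(Intercept)` = 1, X)
}

#' Per-variant genome-wide association scan
#'
#' For every variant, fits an ordinary-least-squares regression of the
#' trait on the effect-allele dosage plus covariates
#' (`trait ~ dosage + sex + age + PC1..PCk` by default) over the samples
#' with a non-missing dosage for that variant. Samples with an incomplete
#' trait or covariate are dropped up front (with a message). Variants
#' monomorphic within the analysis subset are excluded from the output;
#' their count is attached as attribute `"n_monomorphic"`. Two-sided
#' p-values use the t-distribution with the residual degrees of freedom.
#'
#' @param g A [genotype_matrix()].
#' @param ph A phenotype table (data frame with `sample_id`).
#' @param pcs A `pca_basis` (its Tracy-Widom-selected components are used
#'   as covariates), a loadings matrix with sample rownames, or `NULL`.
#' @param sample_subset Optional character vector of sample ids to scan.
#' @param trait Name of the trait column.
#' @param covariates Phenotype columns used as covariates; factors are
#'   coded 0/1.
#' @param backend Bookkeeping label stored in the output ("glm" by
#'   default); all backends fit the same additive linear model.
#' @return A data frame of class `summary_stats` with columns
#'   `variant_id, chromosome, base_pair_location, effect_allele,
#'   other_allele, beta, standard_error, p_value, n`.
#' @export
gwas_scan <- function(g, ph, pcs = NULL, sample_subset = NULL,
                      trait = "height_cm",
                      covariates = c("sex", "age_years"),
                      backend = "glm") {
  samples <- if (is.null(sample_subset)) sample_ids(g) else sample_subset
  if (length(samples) == 0) stop("empty sample subset", call. = FALSE)
  rows <- match(samples, ph$sample_id)
  if (anyNA(rows)) stop("sample(s) absent from the phenotype table", call. = FALSE)
  y <- as.numeric(ph[[trait]][rows])
  X <- .covariate_matrix(ph, covariates, pcs, samples)
  complete <- stats::complete.cases(cbind(y, X))
  if (!all(complete)) {
    message(sum(!complete), " sample(s) dropped for incomplete trait/covariates")
    samples <- samples[complete]
    y <- y[complete]
    X <- X[complete, , drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  idx <- match(samples, sample_ids(g))
  D <- if (identical(idx, seq_len(nrow(g$dosage)))) g$dosage else
    g$dosage[idx, , drop = FALSE]
  fit <- .gwas_ols_cpp(D, X, y)
  tval <- fit$beta / fit$se
  p <- 2 * stats::pt(-abs(tval), fit$df)
  out <- data.frame(variant_id = g$variants$id,
                    chromosome = g$variants$chrom,
                    base_pair_location = g$variants$pos,
                    effect_allele = g$variants$effect_allele,
                    other_allele = g$variants$other_allele,
                    beta = fit$beta,
                    standard_error = fit$se,
                    p_value = p,
                    n = as.integer(fit$n),
                    stringsAsFactors = FALSE)
  mono <- is.na(out$beta)
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "trait") <- trait
  attr(out, "covariates") <- colnames(X)[-1L]
  attr(out, "backend") <- backend
  attr(out, "n_monomorphic") <- sum(mono)
  out
}
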