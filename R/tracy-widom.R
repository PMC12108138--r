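#' Tracy-Widom (beta = 1) distribution function and quantiles
#'
#' Distribution of the standardized largest eigenvalue of a null (GOE)
#' covariance matrix, evaluated by monotone interpolation of a bundled
#' high-resolution table of the cumulative distribution (see
#' `R/tw-table.R` for its provenance). Values outside the tabulated range
#' are clamped to the table ends.
#'
#' @param q,p Vector of quantiles / probabilities.
#' @return `ptw1` returns cumulative probabilities, `qtw1` quantiles.
#' @export
ptw1 <- function(q) {
  out <- stats::approx(.tw1_s, .tw1_cdf, xout = q, rule = 2)$y
  out
}

#' @rdname ptw1
#' @export
qtw1 <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must be in [0, 1]", call. = FALSE)
  stats::approx(.tw1_cdf, .tw1_s, xout = pmin(pmax(p, min(.tw1_cdf)),
                                              max(.tw1_cdf)), rule = 2)$y
}

#' Count significant principal components by sequential Tracy-Widom tests
#'
#' Implements the Patterson-style sequential procedure: for the leading
#' eigenvalue of the remaining spectrum, an effective marker number is
#' estimated from the eigenvalue moments,
#' `n_hat = (m + 1) S1^2 / (m S2 - S1^2)` with `S1 = sum(lambda)`,
#' `S2 = sum(lambda^2)` and `m` the number of remaining eigenvalues; the
#' normalized statistic
#' `(m lambda_1 / S1 - mu) / sigma` is compared against the upper-alpha
#' quantile of the Tracy-Widom (beta = 1) law, where
#' `mu = (sqrt(n_hat - 1) + sqrt(m))^2 / n_hat` and
#' `sigma = (sqrt(n_hat - 1) + sqrt(m)) / n_hat *
#'  (1/sqrt(n_hat - 1) + 1/sqrt(m))^(1/3)`.
#' Testing proceeds down the spectrum and stops at the first
#' non-significant eigenvalue; the count of consecutive significant
#' leading eigenvalues (capped at `max_pc`) is returned.
#'
#' @param eigenvalues Non-negative eigenvalues sorted descending.
#'   Near-zero trailing eigenvalues (below `1e-8` of the largest) are
#'   dropped before testing.
#' @param n_samples Number of samples the spectrum came from (>= 3).
#' @param n_variants Number of variants (informational; the effective
#'   marker number is estimated from the spectrum itself).
#' @param alpha Significance level (default 0.05).
#' @param max_pc Cap on the number of selected components (default 20).
#' @return Integer count of selected components, with the per-eigenvalue
#'   Tracy-Widom statistics of the tested leading eigenvalues attached as
#'   attribute `"tw_statistics"`.
#' @export
tracy_widom_select <- function(eigenvalues, n_samples, n_variants = NULL,
                               alpha = 0.05, max_pc = 20) {
  if (n_samples < 3) stop("at least 3 samples required", call. = FALSE)
  .check_fraction(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  max_pc <- .check_count(max_pc, "max_pc", min = 0)
  ev <- eigenvalues
  if (is.unsorted(rev(ev))) stop("'eigenvalues' must be sorted descending", call. = FALSE)
  ev <- ev[ev > 1e-8 * max(ev, 0)]
  crit <- qtw1(1 - alpha)
  k <- 0L
  tw <- numeric(0)
  while (k < max_pc && k < length(ev) - 2L) {
    lam <- ev[(k + 1L):length(ev)]
    m <- length(lam)
    S1 <- sum(lam); S2 <- sum(lam^2)
    denom <- m * S2 - S1^2
    if (denom <= 0) break
    nhat <- (m + 1) * S1^2 / denom
    if (nhat <= 1) break
    l <- m * lam[1] / S1
    mu <- (sqrt(nhat - 1) + sqrt(m))^2 / nhat
    sg <- (sqrt(nhat - 1) + sqrt(m)) / nhat *
      (1 / sqrt(nhat - 1) + 1 / sqrt(m))^(1 / 3)
    stat <- (l - mu) / sg
    tw <- c(tw, stat)
    if (stat <= crit) break
    k <- k + 1L
  }
  structure(k, tw_statistics = tw)
}

#' Principal component analysis of a genotype matrix
#'
#' Eigen-decomposition of the sample-sample covariance of mean-imputed,
#' Patterson-scaled dosages (each variant centred at `2 p-hat` and
#' divided by `sqrt(2 p-hat (1 - p-hat))`); the covariance is
#' `Z Z' / m` over the `m` (pruned) variants used. The full eigenvalue
#' spectrum is retained and the number of significant components is
#' selected with [tracy_widom_select()].
#'
#' @param g A [genotype_matrix()].
#' @param pruned Character vector of variant ids to use (typically from
#'   [ld_prune()]); `NULL` uses all variants.
#' @param alpha Significance level for component selection.
#' @param max_pc Cap on the number of selected components.
#' @return An object of class `pca_basis`: `eigenvalues` (descending),
#'   `loadings` (samples x K orthonormal columns, K = max(n_selected,
#'   min(10, rank))), `n_selected`, `tw_statistics`, `alpha`,
#'   `n_samples`, `n_variants`.
#' @export
genotype_pca <- function(g, pruned = NULL, alpha = 0.05, max_pc = 20) {
  if (!is.null(pruned)) {
    if (length(pruned) == 0) stop("'pruned' is empty", call. = FALSE)
    g <- subset_genotypes(g, variants = pruned)
  }
  n <- nrow(g$dosage)
  if (n < 3) stop("at least 3 samples required", call. = FALSE)
  Z <- standardize_dosage(g, "patterson")
  keep <- colSums(Z != 0) > 0
  if (!any(keep)) stop("all variants have zero variance", call. = FALSE)
  if (!all(keep)) Z <- Z[, keep, drop = FALSE]
  m <- ncol(Z)
  rank_max <- min(n - 1L, m)
  if (m <= n) {
    E <- eigen(crossprod(Z) / m, symmetric = TRUE)
    lam <- pmax(E$values[seq_len(rank_max)], 0)
    ns <- tracy_widom_select(lam, n_samples = n, n_variants = m,
                             alpha = alpha, max_pc = max_pc)
    K <- max(as.integer(ns), min(10L, rank_max))
    vecs_right <- E$vectors[, seq_len(K), drop = FALSE]
    U <- Z %*% vecs_right
    lamK <- lam[seq_len(K)]
    nz <- lamK > 1e-12 * max(lam[1], 1e-300)
    U[, nz] <- sweep(U[, nz, drop = FALSE], 2, sqrt(lamK[nz] * m), "/")
    U[, !nz] <- 0
  } else {
    E <- eigen(tcrossprod(Z) / m, symmetric = TRUE)
    lam <- pmax(E$values[seq_len(rank_max)], 0)
    ns <- tracy_widom_select(lam, n_samples = n, n_variants = m,
                             alpha = alpha, max_pc = max_pc)
    K <- max(as.integer(ns), min(10L, rank_max))
    U <- E$vectors[, seq_len(K), drop = FALSE]
  }
  loadings <- U
  rownames(loadings) <- rownames(g$dosage)
  colnames(loadings) <- paste0("PC", seq_len(K))
  structure(list(eigenvalues = lam,
                 loadings = loadings,
                 n_selected = as.integer(ns),
                 tw_statistics = attr(ns, "tw_statistics"),
                 alpha = alpha,
                 n_samples = n, n_variants = m),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("pca_basis: %d samples, %d variants; %d significant PC(s) at alpha = %g\n",
              x$n_samples, x$n_variants, x$n_selected, x$alpha))
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Selected principal components as a covariate matrix
#'
#' @param basis A `pca_basis`.
#' @param samples Optional sample ids to extract rows for.
#' @param k Number of components; defaults to the Tracy-Widom selection.
#' @return Numeric matrix (possibly zero columns).
#' @export
pc_covariates <- function(basis, samples = NULL, k = NULL) {
  if (is.null(k)) k <- basis$n_selected
  k <- min(k, ncol(basis$loadings))
  out <- basis$loadings[, seq_len(k), drop = FALSE]
  if (!is.null(samples)) {
    idx <- match(samples, rownames(basis$loadings))
    if (anyNA(idx)) stop("unknown sample id(s) in PC extraction", call. = FALSE)
    out <- out[idx, , drop = FALSE]
  }
  out
}
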