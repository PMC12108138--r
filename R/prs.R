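#' Weighted variant list defining a polygenic score
#'
#' @param entries Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `weight` (and optionally `p_source`).
#' @param p_threshold The p-value inclusion threshold the model was
#'   selected at (`NA` for aggregated models).
#' @param source Free-text label of the summary-statistics source.
#' @return An object of class `prs_model`.
#' @export
prs_model <- function(entries, p_threshold = NA_real_, source = "unknown") {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "weight")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("'entries' lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(entries$variant_id))
    stop("model variant ids must be unique", call. = FALSE)
  if (!"p_source" %in% names(entries)) entries$p_source <- NA_real_
  rownames(entries) <- NULL
  structure(list(entries = entries, p_threshold = p_threshold,
                 source = source, n_snps = nrow(entries)),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model: %d variant(s), source '%s'", x$n_snps, x$source))
  if (!is.na(x$p_threshold)) cat(sprintf(", p-threshold %g", x$p_threshold))
  cat("\n")
  invisible(x)
}

#' @export
coef.prs_model <- function(object, ...) {
  stats::setNames(object$entries$weight, object$entries$variant_id)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the smallest-p unclaimed variant as an index variant
#' and claims every unclaimed variant within `clump_window_kb` kilobases
#' whose squared correlation with it (in the LD reference) exceeds
#' `clump_r2`. Ties in p are broken by ascending genomic position, then
#' lexicographic variant id. Variants absent from the LD reference are
#' kept as their own clump, with a message. Returns the index variants
#' only, in selection (ascending p) order.
#'
#' @param ss A `summary_stats` data frame (see [gwas_scan()]).
#' @param ld_ref A [genotype_matrix()] supplying dosages for correlation.
#' @param params A [ct_params()].
#' @return Character vector of index variant ids.
#' @export
clump <- function(ss, ld_ref, params = ct_params()) {
  stopifnot(inherits(params, "ct_params"))
  ord <- order(ss$p_value, ss$base_pair_location, ss$variant_id)
  ss <- ss[ord, , drop = FALSE]
  present <- ss$variant_id %in% variant_ids(ld_ref)
  if (!all(present))
    message(sum(!present), " variant(s) absent from the LD reference; kept as own clump")
  Z <- NULL
  zcol <- rep(NA_integer_, nrow(ss))
  if (any(present)) {
    sub <- subset_genotypes(ld_ref, variants = ss$variant_id[present])
    Z <- standardize_dosage(sub, "unit")
    zcol[present] <- match(ss$variant_id[present], variant_ids(sub))
  }
  n <- if (!is.null(Z)) nrow(Z) else 0L
  win <- params$clump_window_kb * 1000
  claimed <- rep(FALSE, nrow(ss))
  index <- character(0)
  for (i in seq_len(nrow(ss))) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    index <- c(index, ss$variant_id[i])
    if (is.na(zcol[i])) next
    cand <- which(!claimed & !is.na(zcol) &
                    ss$chromosome == ss$chromosome[i] &
                    abs(ss$base_pair_location - ss$base_pair_location[i]) <= win)
    if (!length(cand)) next
    r <- crossprod(Z[, zcol[cand], drop = FALSE], Z[, zcol[i]]) / (n - 1)
    claimed[cand[r^2 > params$clump_r2]] <- TRUE
  }
  index
}

# strand-ambiguous: the two alleles are reverse complements of each other
.is_ambiguous <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

# Match model entries to the columns of a genotype matrix, flipping
# dosages whose allele labels are swapped relative to the model.
# Returns NULL entries when nothing matches.
.match_model <- function(model, g) {
  e <- model$entries
  idx <- match(e$variant_id, variant_ids(g))
  hit <- !is.na(idx)
  flip <- rep(FALSE, nrow(e))
  if (any(hit)) {
    hit_rows <- which(hit)
    v <- g$variants[idx[hit], , drop = FALSE]
    # aligned when effect alleles agree; flipped when the genotype's other
    # allele is the model's effect allele; anything else is unmatchable
    same <- v$effect_allele == e$effect_allele[hit]
    swapped <- !same & v$other_allele == e$effect_allele[hit]
    bad <- !same & !swapped
    hit[hit_rows[bad]] <- FALSE
    flip[hit_rows[swapped]] <- TRUE
  }
  n_unmatched <- sum(!hit)
  if (n_unmatched > 0)
    message(n_unmatched, " model variant(s) unmatchable in the scored genotypes; dropped")
  if (n_unmatched > 0.5 * nrow(e))
    stop("more than half of the model variants cannot be matched to the genotypes",
         call. = FALSE)
  list(rows = which(hit), cols = idx[hit], flip = flip[hit])
}

#' Score individuals with a PRS model
#'
#' The raw score follows the average-per-observed-allele convention:
#' `raw_i = sum_j beta_j G_ij / (2 m_i)`, where `m_i` is the number of
#' model variants with a non-missing dosage for sample `i` and missing
#' dosages contribute the variant's expected dosage `2 p-hat` (allele
#' frequency taken from the scored cohort). Variants whose allele labels
#' are swapped relative to the model have their dosage flipped to the
#' model's effect allele; unmatchable variants are dropped with a message
#' (a hard error if more than half drop). `average = FALSE` gives the
#' plain weighted sum instead.
#'
#' @param model A [prs_model()].
#' @param g A [genotype_matrix()].
#' @param average Divide by twice the observed-variant count (default
#'   `TRUE`).
#' @param drop_ambiguous Drop strand-ambiguous (A/T, C/G) variants
#'   instead of merely flagging them. The default (`FALSE`) keeps them,
#'   appropriate when model and genotypes are known to share a strand
#'   convention; set `TRUE` for models imported from external sources.
#' @return A data frame of class `prs_profile` with columns `sample_id`,
#'   `raw_score`, `scaled_score` (min-max scaled to `[0, 1]`; 0.5 when
#'   all raw scores are equal) and `n_alleles_observed`.
#' @export
prs_score <- function(model, g, average = TRUE, drop_ambiguous = FALSE) {
  mm <- .match_model(model, g)
  amb <- .is_ambiguous(g$variants$effect_allele[mm$cols],
                       g$variants$other_allele[mm$cols])
  if (any(amb)) {
    message(sum(amb), " strand-ambiguous (A/T, C/G) variant(s) ",
            if (drop_ambiguous) "dropped" else "kept")
    if (drop_ambiguous) {
      mm$rows <- mm$rows[!amb]; mm$cols <- mm$cols[!amb]
      mm$flip <- mm$flip[!amb]
    }
  }
  n <- nrow(g$dosage)
  if (length(mm$cols) == 0) stop("no model variant matches the genotypes", call. = FALSE)
  D <- g$dosage[, mm$cols, drop = FALSE]
  D[, mm$flip] <- 2 - D[, mm$flip, drop = FALSE]
  w <- model$entries$weight[mm$rows]
  obs <- (!is.na(D)) %*% rep(1, ncol(D))
  p <- colMeans(D, na.rm = TRUE) / 2
  if (anyNA(D)) {
    na_idx <- which(is.na(D))
    D[na_idx] <- 2 * p[(na_idx - 1L) %/% n + 1L]
  }
  raw <- drop(D %*% w)
  if (average) raw <- ifelse(obs > 0, raw / (2 * obs), 0)
  rng <- range(raw)
  scaled <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else rep(0.5, n)
  out <- data.frame(sample_id = rownames(g$dosage), raw_score = raw,
                    scaled_score = scaled,
                    n_alleles_observed = as.integer(2 * obs),
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_profile", "data.frame")
  out
}

# Incremental R2 of adding score columns S (n x T) to y ~ X, via the
# Frisch-Waugh-Lovell decomposition; X must include the intercept.
# Returns list(inc (length T), r2_base, partial_r (length T), df).
.incremental_r2 <- function(y, X, S) {
  qx <- qr(X)
  Q <- qr.Q(qx)
  yt <- y - Q %*% crossprod(Q, y)
  St <- S - Q %*% crossprod(Q, S)
  tss <- sum((y - mean(y))^2)
  ss_s <- colSums(St^2)
  num <- drop(crossprod(St, yt))
  inc <- ifelse(ss_s > tss * 1e-14, num^2 / (ss_s * tss), 0)
  ryy <- sum(yt^2)
  partial <- ifelse(ss_s > tss * 1e-14 & ryy > 0,
                    num / sqrt(ss_s * ryy), 0)
  list(inc = inc, r2_base = 1 - ryy / tss, partial_r = partial,
       df = length(y) - ncol(X) - 1L, Q = Q, yt = yt, St = St, tss = tss)
}

#' Derive the best clumping-and-thresholding PRS on a target set
#'
#' After clumping the summary statistics against the target genotypes,
#' a score is built for every p-value threshold on the grid from the
#' clumped variants with `p <= threshold`, and the trait is regressed on
#' `score + covariates` in the target samples. The model maximizing the
#' incremental R2 (the R2 of the regression with the score minus the R2
#' without it) is returned, together with an empirical p-value: the
#' fraction of `n_permutations` phenotype permutations whose own
#' best-threshold incremental R2 is at least the observed one, guarding
#' the threshold scan against overfitting.
#'
#' @param ss `summary_stats` from the (disjoint) source set.
#' @param target_g Target-set [genotype_matrix()]; also the LD reference
#'   for clumping.
#' @param target_ph Phenotype table covering the target samples.
#' @param covariates Phenotype columns used as covariates.
#' @param pcs Optional `pca_basis` or loadings matrix for PC covariates.
#' @param params A [ct_params()].
#' @param trait Trait column name.
#' @param seed Integer seed for the permutations.
#' @return A list of class `prs_fit`: `model` (a [prs_model()]),
#'   `grid` (per-threshold n_snps and incremental R2), `incremental_r2`,
#'   `empirical_p`, `prs_p` (t-test p of the score term), `r2_base`,
#'   `r2_full`.
#' @export
derive_best_prs <- function(ss, target_g, target_ph,
                            covariates = c("sex", "age_years"), pcs = NULL,
                            params = ct_params(), trait = "height_cm",
                            seed = 1) {
  kept <- clump(ss, target_g, params)
  ssk <- ss[match(kept, ss$variant_id), , drop = FALSE]
  grid <- params$p_grid
  if (!any(ssk$p_value <= max(grid)))
    stop("no variant passes the loosest p-value threshold", call. = FALSE)
  samples <- intersect(sample_ids(target_g), target_ph$sample_id)
  gT <- subset_genotypes(target_g, samples = samples, variants = kept)
  y <- as.numeric(target_ph[[trait]][match(samples, target_ph$sample_id)])
  X <- .covariate_matrix(target_ph, covariates, pcs, samples)
  ok <- stats::complete.cases(cbind(y, X))
  if (!all(ok)) {
    samples <- samples[ok]; y <- y[ok]; X <- X[ok, , drop = FALSE]
    gT <- subset_genotypes(gT, samples = samples)
  }
  n <- length(y)

  D <- gT$dosage
  W <- !is.na(D)
  p <- colMeans(D, na.rm = TRUE) / 2
  if (anyNA(D)) {
    na_idx <- which(is.na(D))
    D[na_idx] <- 2 * p[(na_idx - 1L) %/% n + 1L]
  }
  Mthr <- outer(ssk$p_value, grid, "<=")          # K x T inclusion mask
  nsnp <- colSums(Mthr)
  Num <- D %*% (ssk$beta * Mthr)
  Obs <- W %*% Mthr
  S <- ifelse(Obs > 0, Num / (2 * Obs), 0)

  fw <- .incremental_r2(y, X, S)
  use <- nsnp > 0
  inc <- ifelse(use, fw$inc, -Inf)
  best <- which.max(inc)
  best_inc <- fw$inc[best]

  # permutation empirical p-value over the whole threshold scan
  emp_p <- NA_real_
  B <- params$n_permutations
  if (B > 0) {
    set.seed(seed)
    Yp <- matrix(y[sample.int(n)], n, 1)
    if (B > 1) Yp <- cbind(Yp, replicate(B - 1, y[sample.int(n)]))
    Yt <- Yp - fw$Q %*% crossprod(fw$Q, Yp)
    ss_s <- colSums(fw$St^2)
    num <- crossprod(fw$St, Yt)                    # T x B
    ss_ok <- ss_s > fw$tss * 1e-14
    incp <- num^2 / ifelse(ss_ok, ss_s, Inf) / fw$tss
    incp[!use, ] <- -Inf
    best_perm <- apply(incp, 2, max)
    emp_p <- mean(best_perm >= best_inc)
  }
  r <- fw$partial_r[best]
  tstat <- r * sqrt(fw$df / pmax(1 - r^2, 1e-300))
  prs_p <- 2 * stats::pt(-abs(tstat), fw$df)

  sel <- which(Mthr[, best])
  entries <- data.frame(variant_id = ssk$variant_id[sel],
                        chrom = ssk$chromosome[sel],
                        pos = ssk$base_pair_location[sel],
                        effect_allele = ssk$effect_allele[sel],
                        weight = ssk$beta[sel],
                        p_source = ssk$p_value[sel],
                        stringsAsFactors = FALSE)
  model <- prs_model(entries, p_threshold = grid[best],
                     source = attr(ss, "backend") %||% "glm")
  structure(list(model = model,
                 grid = data.frame(threshold = grid, n_snps = nsnp,
                                   incremental_r2 = fw$inc),
                 incremental_r2 = best_inc,
                 empirical_p = emp_p,
                 prs_p = prs_p,
                 r2_base = fw$r2_base,
                 r2_full = fw$r2_base + best_inc),
            class = "prs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
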