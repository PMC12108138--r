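#' Run the iterative bootstrap PRS ensemble
#'
#' Repeats, `n_iterations` times with fresh random 80/20 partitions
#' (sampling without replacement): variant and sample QC on the source
#' set, LD pruning, PCA with Tracy-Widom component selection, a
#' per-variant association scan with sex/age/PC covariates, and
#' derivation of the best clumping-and-thresholding PRS on the target
#' set. The per-iteration incremental R2 values form the baseline
#' distribution against which aggregated candidates are later compared.
#'
#' Per-iteration seeds are derived from the master seed with a single
#' `sample.int()` draw, so the whole ensemble is reproducible. Failed
#' iterations are recorded and skipped; the run aborts when more than
#' 10% fail.
#'
#' @param genotypes Post-QC [genotype_matrix()] for the whole cohort.
#' @param phenotypes Phenotype table covering the cohort.
#' @param trait,covariates Trait and covariate column names.
#' @param n_iterations Number of resampling iterations (default 100).
#' @param split Source fraction of each partition (default 0.8; source
#'   size is `floor(split * N)`).
#' @param qc,prune,ct Parameter objects ([qc_thresholds()],
#'   [prune_params()], [ct_params()]).
#' @param alpha,max_pc Tracy-Widom selection level and cap.
#' @param recompute_pca Recompute QC/pruning/PCA on every source set
#'   (default `TRUE`); otherwise the whole-cohort PC loadings are reused.
#' @param whole_pca Optional precomputed whole-cohort `pca_basis` used
#'   for target-set covariates (computed here when `NULL`).
#' @param seed Integer master seed.
#' @param progress Print one line per iteration.
#' @return An object of class `prs_ensemble`: `records` (one list per
#'   successful iteration with the partition, best model, per-variant
#'   source betas, incremental R2, empirical and score p-values),
#'   `baseline_r2`, `failures`, `whole_pca`, and the configuration.
#' @export
run_ensemble <- function(genotypes, phenotypes, trait = "height_cm",
                         covariates = c("sex", "age_years"),
                         n_iterations = 100, split = 0.8,
                         qc = qc_thresholds(), prune = prune_params(),
                         ct = ct_params(), alpha = 0.05, max_pc = 20,
                         recompute_pca = TRUE, whole_pca = NULL,
                         seed = 1, progress = FALSE) {
  n_iterations <- .check_count(n_iterations, "n_iterations")
  .check_fraction(split, "split", 0, 1, lo_open = TRUE, hi_open = TRUE)
  N <- nrow(genotypes$dosage)
  ids <- sample_ids(genotypes)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)
  if (is.null(whole_pca)) {
    pruned <- ld_prune(genotypes, prune)
    whole_pca <- genotype_pca(genotypes, pruned, alpha = alpha, max_pc = max_pc)
  }
  records <- vector("list", n_iterations)
  failures <- list()
  for (i in seq_len(n_iterations)) {
    res <- tryCatch({
      set.seed(iter_seeds[i])
      src <- sort(sample.int(N, floor(split * N)))
      tgt <- setdiff(seq_len(N), src)
      g_src <- subset_genotypes(genotypes, samples = src)
      fv <- filter_variants(g_src, qc)
      fs <- filter_samples(fv$genotypes, qc)
      g_src <- fs$genotypes
      if (recompute_pca) {
        pruned_src <- ld_prune(g_src, prune)
        pca_src <- genotype_pca(g_src, pruned_src, alpha = alpha, max_pc = max_pc)
      } else {
        pca_src <- whole_pca
      }
      ss <- gwas_scan(g_src, phenotypes, pcs = pca_src, trait = trait,
                      covariates = covariates)
      g_tgt <- subset_genotypes(genotypes, samples = tgt,
                                variants = variant_ids(g_src))
      fit <- derive_best_prs(ss, g_tgt, phenotypes, covariates = covariates,
                             pcs = whole_pca, params = ct, trait = trait,
                             seed = iter_seeds[i])
      list(iteration = i,
           source_ids = ids[src], target_ids = ids[tgt],
           model = fit$model,
           beta = stats::setNames(ss$beta, ss$variant_id),
           incremental_r2 = fit$incremental_r2,
           empirical_p = fit$empirical_p,
           prs_p = fit$prs_p,
           n_pcs_source = pca_src$n_selected)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(iteration = i,
                                                message = conditionMessage(res))
    } else {
      records[[i]] <- res
    }
    if (progress)
      message(sprintf("iteration %d/%d %s", i, n_iterations,
                      if (inherits(res, "error")) "FAILED" else
                        sprintf("incremental R2 = %.4f", res$incremental_r2)))
  }
  records <- Filter(Negate(is.null), records)
  if (length(failures) > 0.1 * n_iterations)
    stop(sprintf("%d of %d iterations failed (first: %s)", length(failures),
                 n_iterations, failures[[1]]$message), call. = FALSE)
  structure(list(records = records,
                 baseline_r2 = vapply(records, `[[`, numeric(1), "incremental_r2"),
                 failures = failures,
                 whole_pca = whole_pca,
                 genotypes = genotypes, phenotypes = phenotypes,
                 trait = trait, covariates = covariates,
                 config = list(n_iterations = n_iterations, split = split,
                               qc = qc, prune = prune, ct = ct,
                               alpha = alpha, max_pc = max_pc,
                               recompute_pca = recompute_pca, seed = seed)),
            class = "prs_ensemble")
}

#' @export
print.prs_ensemble <- function(x, ...) {
  cat(sprintf("prs_ensemble: %d/%d successful iterations\n",
              length(x$records), x$config$n_iterations))
  cat(sprintf("  baseline incremental R2: mean %.4f, sd %.4f\n",
              mean(x$baseline_r2), stats::sd(x$baseline_r2)))
  invisible(x)
}

#' Frequency of appearance of variants across best per-iteration models
#'
#' Counts, for every variant, the number of iterations whose best PRS
#' contained it (once per iteration regardless of weight).
#'
#' @param ensemble A `prs_ensemble`, or a plain list of iteration records.
#' @return Named integer vector of appearance counts, sorted decreasing.
#' @export
aggregate_frequencies <- function(ensemble) {
  records <- if (inherits(ensemble, "prs_ensemble")) ensemble$records else ensemble
  if (length(records) == 0) stop("no successful iterations to aggregate", call. = FALSE)
  ids <- unlist(lapply(records, function(r) unique(r$model$entries$variant_id)),
                use.names = FALSE)
  tab <- sort(table(ids), decreasing = TRUE)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts
}

#' Build frequency-thresholded candidate PRSs
#'
#' For every distinct appearance frequency `f >= min_freq` at which the
#' variant set changes, forms the candidate set of variants appearing in
#' at least `f` best models, and recomputes its incremental R2 once per
#' iteration: the fixed set is scored on that iteration's target samples
#' with that iteration's source-set effects *as returned in that
#' iteration's best PRS* -- i.e. the variants of `snp_set` that are also
#' in iteration `i`'s best model, with that model's weights -- and the
#' trait is regressed on score plus covariates. Restricting each
#' iteration's contribution to its own model keeps iteration `i`'s value
#' a function of iteration `i`'s source/target partition alone, so the
#' per-candidate distribution stays comparable with the per-iteration
#' baseline. Candidate sets are nested: the set at a higher cut-off is a
#' subset of the set at a lower one.
#'
#' @param ensemble A `prs_ensemble` from [run_ensemble()].
#' @param min_freq Minimum appearance count for inclusion (the
#'   conventional floor is 10 of 100 iterations).
#' @return An object of class `prs_candidates`: a list of `candidate_prs`
#'   objects (`min_freq`, `snp_set`, `r2` per iteration, `mean_r2`,
#'   `sd_r2`, `n_snps`), plus a summary `table`.
#' @export
build_candidates <- function(ensemble, min_freq = 10) {
  stopifnot(inherits(ensemble, "prs_ensemble"))
  min_freq <- .check_count(min_freq, "min_freq")
  counts <- aggregate_frequencies(ensemble)
  cutoffs <- sort(unique(counts[counts >= min_freq]))
  if (length(cutoffs) == 0)
    return(structure(list(candidates = list(),
                          table = data.frame(min_freq = integer(0),
                                             n_snps = integer(0),
                                             mean_r2 = numeric(0),
                                             sd_r2 = numeric(0))),
                     class = "prs_candidates"))
  union_ids <- names(counts)[counts >= cutoffs[1]]
  sets <- lapply(cutoffs, function(f) names(counts)[counts >= f])
  ph <- ensemble$phenotypes
  gen <- ensemble$genotypes
  r2 <- matrix(NA_real_, length(cutoffs), length(ensemble$records))
  for (i in seq_along(ensemble$records)) {
    rec <- ensemble$records[[i]]
    tgt <- rec$target_ids
    gT <- subset_genotypes(gen, samples = tgt,
                           variants = intersect(union_ids, variant_ids(gen)))
    u <- variant_ids(gT)
    mdl <- rec$model$entries
    w <- mdl$weight[match(u, mdl$variant_id)]  # NA when not in this model
    present <- !is.na(w)
    w0 <- ifelse(present, w, 0)
    M <- vapply(cutoffs, function(f) (counts[u] >= f) & present,
                logical(length(u)))
    M <- matrix(M, nrow = length(u))
    D <- gT$dosage
    W <- !is.na(D)
    p <- colMeans(D, na.rm = TRUE) / 2
    if (anyNA(D)) {
      na_idx <- which(is.na(D))
      D[na_idx] <- 2 * p[(na_idx - 1L) %/% nrow(D) + 1L]
    }
    Num <- D %*% (w0 * M)
    Obs <- W %*% M
    S <- ifelse(Obs > 0, Num / (2 * Obs), 0)
    y <- as.numeric(ph[[ensemble$trait]][match(rownames(D), ph$sample_id)])
    X <- .covariate_matrix(ph, ensemble$covariates, ensemble$whole_pca,
                           rownames(D))
    ok <- stats::complete.cases(cbind(y, X))
    fw <- .incremental_r2(y[ok], X[ok, , drop = FALSE], S[ok, , drop = FALSE])
    r2[, i] <- fw$inc
  }
  cands <- lapply(seq_along(cutoffs), function(ci) {
    structure(list(min_freq = as.integer(cutoffs[ci]),
                   snp_set = sets[[ci]],
                   r2 = r2[ci, ],
                   mean_r2 = mean(r2[ci, ]),
                   sd_r2 = stats::sd(r2[ci, ]),
                   n_snps = length(sets[[ci]])),
              class = "candidate_prs")
  })
  keep <- vapply(cands, function(cc) cc$n_snps > 0, logical(1))
  cands <- cands[keep]
  tab <- data.frame(min_freq = vapply(cands, `[[`, integer(1), "min_freq"),
                    n_snps = vapply(cands, `[[`, integer(1), "n_snps"),
                    mean_r2 = vapply(cands, `[[`, numeric(1), "mean_r2"),
                    sd_r2 = vapply(cands, `[[`, numeric(1), "sd_r2"))
  structure(list(candidates = cands, table = tab), class = "prs_candidates")
}

#' @export
print.prs_candidates <- function(x, ...) {
  cat("prs_candidates:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# strict local maxima over a sequence; endpoints compare to their single
# neighbour; a lone element is a maximum
.local_maxima <- function(x) {
  k <- length(x)
  if (k == 0) return(integer(0))
  if (k == 1) return(1L)
  left <- c(TRUE, x[-1] > x[-k])
  right <- c(x[-k] > x[-1], TRUE)
  which(left & right)
}

#' Narrow candidates down to local maxima of the incremental-R2 profile
#'
#' Orders candidates by their frequency cut-off and keeps those whose
#' mean incremental R2 is strictly greater than both neighbours'
#' (endpoints compare to their single neighbour).
#'
#' @param candidates A `prs_candidates` object.
#' @return A `prs_candidates` object containing the local maxima.
#' @export
narrow_down <- function(candidates) {
  stopifnot(inherits(candidates, "prs_candidates"))
  if (length(candidates$candidates) == 0)
    stop("no candidates to narrow down", call. = FALSE)
  ord <- order(vapply(candidates$candidates, `[[`, integer(1), "min_freq"))
  cands <- candidates$candidates[ord]
  means <- vapply(cands, `[[`, numeric(1), "mean_r2")
  keep <- .local_maxima(means)
  structure(list(candidates = cands[keep],
                 table = candidates$table[ord, ][keep, , drop = FALSE]),
            class = "prs_candidates")
}

#' Empirical bootstrap p-value of a candidate PRS
#'
#' The fraction of iterations in which the baseline incremental R2
#' exceeded the candidate's mean incremental R2.
#'
#' @param candidate A `candidate_prs` (or its mean incremental R2).
#' @param baseline Numeric vector of per-iteration baseline incremental
#'   R2 values.
#' @return A fraction in `[0, 1]`.
#' @export
bootstrap_p <- function(candidate, baseline) {
  if (length(baseline) == 0) stop("'baseline' is empty", call. = FALSE)
  m <- if (inherits(candidate, "candidate_prs")) candidate$mean_r2 else
    as.numeric(candidate)
  sum(baseline > m) / length(baseline)
}

#' Finalize a candidate PRS with whole-cohort effects
#'
#' Assigns each candidate variant the effect estimated from the
#' whole-cohort summary statistics (same covariates); the variant set is
#' unchanged except that variants missing from the whole-cohort scan are
#' dropped with a warning.
#'
#' @param candidate A `candidate_prs`.
#' @param whole_ss `summary_stats` computed on the total cohort.
#' @return A [prs_model()].
#' @export
finalize_prs <- function(candidate, whole_ss) {
  stopifnot(inherits(candidate, "candidate_prs"))
  idx <- match(candidate$snp_set, whole_ss$variant_id)
  if (all(is.na(idx)))
    stop("no candidate variant is present in the whole-cohort summary statistics",
         call. = FALSE)
  if (anyNA(idx))
    warning(sum(is.na(idx)),
            " candidate variant(s) missing from whole-cohort summary statistics; dropped")
  keep <- which(!is.na(idx))
  idx <- idx[keep]
  entries <- data.frame(variant_id = whole_ss$variant_id[idx],
                        chrom = whole_ss$chromosome[idx],
                        pos = whole_ss$base_pair_location[idx],
                        effect_allele = whole_ss$effect_allele[idx],
                        weight = whole_ss$beta[idx],
                        p_source = whole_ss$p_value[idx],
                        stringsAsFactors = FALSE)
  prs_model(entries, p_threshold = NA_real_,
            source = paste0("whole-cohort/", attr(whole_ss, "backend") %||% "glm"))
}
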