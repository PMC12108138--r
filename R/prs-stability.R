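#' Fit a stability-selected polygenic risk score
#'
#' The central fitting function. Applies cohort-level QC (variant filters
#' before sample filters), runs the iterative bootstrap ensemble
#' ([run_ensemble()]), aggregates the variants of the per-iteration best
#' models by appearance frequency, builds frequency-thresholded candidate
#' scores ([build_candidates()]), narrows them to local maxima of the
#' mean incremental-R2 profile ([narrow_down()]), attaches empirical
#' bootstrap p-values against the per-iteration baseline
#' ([bootstrap_p()]), and finalizes the first narrowed candidate on the
#' frequency-ordered profile (the largest stable set, which under real
#' signal is also the profile's global maximum) with effects
#' re-estimated from a whole-cohort association scan ([finalize_prs()]).
#'
#' @param genotypes A [genotype_matrix()] (raw; QC is applied here).
#' @param phenotypes Phenotype table with `sample_id`, the trait and the
#'   covariates.
#' @param trait,covariates Trait and covariate column names.
#' @param n_iterations Number of resampling iterations (default 100).
#' @param split Source fraction per iteration (default 0.8).
#' @param min_freq Minimum appearance count for a variant to enter the
#'   aggregated candidates; defaults to 10% of `n_iterations` (the
#'   conventional 10-of-100 floor), rounded up.
#' @param qc,prune,ct Parameter objects.
#' @param alpha,max_pc Tracy-Widom selection level and cap.
#' @param recompute_pca Recompute QC/PCA per source set (default `TRUE`).
#' @param seed Integer master seed; fixes partitions and permutations.
#' @param progress Print per-iteration progress.
#' @return An object of class `prs_stability` with, among others:
#'   `final_model` (a [prs_model()]), `final_candidate`, `candidates`,
#'   `narrowed` (both with bootstrap p-values in their tables),
#'   `ensemble`, `freq_table`, `whole_ss`, `pca`, `profile` (the final
#'   score over the QCed cohort), `incremental_r2` and `trait_cor`
#'   (whole-cohort incremental R2 and trait correlation of the final
#'   score), and the QC reports.
#' @seealso [holdout_validate()], [secondary_association()],
#'   [prs_overlap()] for downstream evaluation.
#' @export
prs_stability <- function(genotypes, phenotypes, trait = "height_cm",
                          covariates = c("sex", "age_years"),
                          n_iterations = 100, split = 0.8,
                          min_freq = ceiling(0.1 * n_iterations),
                          qc = qc_thresholds(), prune = prune_params(),
                          ct = ct_params(), alpha = 0.05, max_pc = 20,
                          recompute_pca = TRUE, seed = 1,
                          progress = FALSE) {
  cl <- match.call()
  fv <- filter_variants(genotypes, qc)
  fs <- filter_samples(fv$genotypes, qc)
  g <- fs$genotypes
  ph <- phenotypes[phenotypes$sample_id %in% sample_ids(g), , drop = FALSE]

  pruned <- ld_prune(g, prune)
  whole_pca <- genotype_pca(g, pruned, alpha = alpha, max_pc = max_pc)

  ens <- run_ensemble(g, ph, trait = trait, covariates = covariates,
                      n_iterations = n_iterations, split = split,
                      qc = qc, prune = prune, ct = ct, alpha = alpha,
                      max_pc = max_pc, recompute_pca = recompute_pca,
                      whole_pca = whole_pca, seed = seed,
                      progress = progress)
  freq <- aggregate_frequencies(ens)
  cands <- build_candidates(ens, min_freq = min_freq)
  if (length(cands$candidates) == 0)
    stop("no variant reached the minimum appearance frequency (", min_freq,
         "); lower 'min_freq' or increase 'n_iterations'", call. = FALSE)
  cands$table$bootstrap_p <- vapply(cands$candidates, bootstrap_p,
                                    numeric(1), baseline = ens$baseline_r2)
  narrowed <- narrow_down(cands)
  narrowed$table$bootstrap_p <- vapply(narrowed$candidates, bootstrap_p,
                                       numeric(1), baseline = ens$baseline_r2)

  whole_ss <- gwas_scan(g, ph, pcs = whole_pca, trait = trait,
                        covariates = covariates)
  # Finalize the first local maximum on the frequency-ordered profile
  # (the lowest-cut-off narrowed candidate, i.e. the largest stable set).
  # Under real signal this coincides with the global maximum of the
  # profile; under weak or no signal it guards against promoting a
  # spuriously inflated high-cut-off candidate. All narrowed candidates
  # stay in the fit for inspection.
  final_candidate <- narrowed$candidates[[1]]
  final_model <- finalize_prs(final_candidate, whole_ss)

  profile <- prs_score(final_model, g)
  y <- as.numeric(ph[[trait]][match(profile$sample_id, ph$sample_id)])
  X <- .covariate_matrix(ph, covariates, whole_pca, profile$sample_id)
  ok <- stats::complete.cases(cbind(y, X))
  fw <- .incremental_r2(y[ok], X[ok, , drop = FALSE],
                        matrix(profile$raw_score[ok], ncol = 1))
  structure(list(call = cl,
                 final_model = final_model,
                 final_candidate = final_candidate,
                 candidates = cands,
                 narrowed = narrowed,
                 ensemble = ens,
                 freq_table = freq,
                 whole_ss = whole_ss,
                 pca = whole_pca,
                 qc_reports = list(variant = fv$report, sample = fs$report),
                 profile = profile,
                 incremental_r2 = fw$inc[1],
                 r2_base = fw$r2_base,
                 r2_full = fw$r2_base + fw$inc[1],
                 trait_cor = stats::cor(profile$raw_score[ok], y[ok]),
                 trait = trait, covariates = covariates,
                 genotypes = g, phenotypes = ph,
                 min_freq = min_freq, seed = seed),
            class = "prs_stability")
}

#' @export
print.prs_stability <- function(x, ...) {
  cat("Stability-selected PRS\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\nFinal PRS: %d variants (appearance frequency >= %d of %d iterations)\n",
              x$final_model$n_snps, x$final_candidate$min_freq,
              x$ensemble$config$n_iterations))
  cat(sprintf("Mean incremental R2 over iterations: %.4f (sd %.4f), bootstrap p = %s\n",
              x$final_candidate$mean_r2, x$final_candidate$sd_r2,
              format_empirical_p(bootstrap_p(x$final_candidate,
                                             x$ensemble$baseline_r2),
                                 length(x$ensemble$baseline_r2))))
  cat(sprintf("Whole-cohort incremental R2: %.4f; trait correlation r = %.3f\n",
              x$incremental_r2, x$trait_cor))
  invisible(x)
}

#' @export
summary.prs_stability <- function(object, ...) {
  out <- list(call = object$call,
              n_iterations = object$ensemble$config$n_iterations,
              n_failures = length(object$ensemble$failures),
              baseline = c(mean = mean(object$ensemble$baseline_r2),
                           sd = stats::sd(object$ensemble$baseline_r2)),
              candidates = object$candidates$table,
              narrowed = object$narrowed$table,
              final = data.frame(n_snps = object$final_model$n_snps,
                                 min_freq = object$final_candidate$min_freq,
                                 mean_r2 = object$final_candidate$mean_r2,
                                 sd_r2 = object$final_candidate$sd_r2,
                                 whole_cohort_incremental_r2 = object$incremental_r2,
                                 trait_cor = object$trait_cor),
              n_pcs = object$pca$n_selected)
  class(out) <- "summary.prs_stability"
  out
}

#' @export
print.summary.prs_stability <- function(x, ...) {
  cat("Stability-selected PRS - candidate table\n\n")
  print(x$candidates, row.names = FALSE)
  cat("\nLocal maxima (narrowed candidates):\n")
  print(x$narrowed, row.names = FALSE)
  cat(sprintf("\nBaseline incremental R2: mean %.4f (sd %.4f) over %d iterations (%d failed)\n",
              x$baseline["mean"], x$baseline["sd"], x$n_iterations,
              x$n_failures))
  cat(sprintf("Tracy-Widom selected PCs: %d\n", x$n_pcs))
  cat("\nFinal PRS:\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
coef.prs_stability <- function(object, ...) coef(object$final_model)

#' Score new samples with the fitted PRS
#'
#' @param object A `prs_stability` fit.
#' @param newdata A [genotype_matrix()]; defaults to the training
#'   genotypes.
#' @param type `"raw"` or `"scaled"` scores, or `"profile"` for the full
#'   [prs_score()] data frame.
#' @param ... Unused.
#' @return Numeric vector of scores, or a `prs_profile`.
#' @export
predict.prs_stability <- function(object, newdata = NULL,
                                  type = c("raw", "scaled", "profile"), ...) {
  type <- match.arg(type)
  g <- if (is.null(newdata)) object$genotypes else newdata
  prof <- prs_score(object$final_model, g)
  switch(type,
         raw = stats::setNames(prof$raw_score, prof$sample_id),
         scaled = stats::setNames(prof$scaled_score, prof$sample_id),
         profile = prof)
}

#' @export
fitted.prs_stability <- function(object, ...) {
  stats::setNames(object$profile$raw_score, object$profile$sample_id)
}

#' @export
residuals.prs_stability <- function(object, ...) {
  ph <- object$phenotypes
  y <- as.numeric(ph[[object$trait]][match(object$profile$sample_id,
                                           ph$sample_id)])
  X <- cbind(.covariate_matrix(ph, object$covariates, object$pca,
                               object$profile$sample_id),
             score = object$profile$raw_score)
  ok <- stats::complete.cases(cbind(y, X))
  res <- rep(NA_real_, length(y))
  res[ok] <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])$residuals
  stats::setNames(res, object$profile$sample_id)
}

#' Plot the candidate incremental-R2 profile
#'
#' Mean incremental R2 (+/- one SD) of each frequency-thresholded
#' candidate against its appearance-frequency cut-off, with the baseline
#' mean as a dashed line and the finalized candidate highlighted.
#'
#' @param x A `prs_stability` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prs_stability <- function(x, ...) {
  tab <- x$candidates$table
  ylim <- range(c(tab$mean_r2 - tab$sd_r2, tab$mean_r2 + tab$sd_r2,
                  x$ensemble$baseline_r2))
  graphics::plot(tab$min_freq, tab$mean_r2, type = "b", pch = 19,
                 xlab = "appearance-frequency cut-off",
                 ylab = "incremental R2", ylim = ylim, ...)
  graphics::arrows(tab$min_freq, tab$mean_r2 - tab$sd_r2,
                   tab$min_freq, tab$mean_r2 + tab$sd_r2,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  graphics::abline(h = mean(x$ensemble$baseline_r2), lty = 2)
  graphics::points(x$final_candidate$min_freq, x$final_candidate$mean_r2,
                   pch = 1, cex = 2, col = "red3")
  invisible(x)
}

#' Format an empirical p-value without printing a literal zero
#'
#' An empirical p of 0 only means "never exceeded in `n` draws"; it is
#' reported as `< 1/n`.
#'
#' @param p Empirical p-value(s).
#' @param n Number of permutations/iterations behind the estimate.
#' @return Character vector.
#' @export
format_empirical_p <- function(p, n) {
  ifelse(p == 0, sprintf("< %g", 1 / n), sprintf("%g", p))
}
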