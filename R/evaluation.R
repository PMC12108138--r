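#' Hold-out validation of a PRS model
#'
#' Repeatedly draws a random hold-out fraction of the cohort, scores it
#' with the (already finalized) model, and fits two regressions on the
#' hold-out: `trait ~ covariates + PCs + PRS` and the same model without
#' the PRS. Records the full-model R2, the incremental R2, the Pearson
#' correlation between score and trait, and the regression coefficient
#' of the min-max-scaled score with its p-value, and aggregates them
#' over the repeats.
#'
#' @param model A [prs_model()].
#' @param genotypes,phenotypes Cohort data.
#' @param fraction Hold-out fraction in `(0, 1)` (default 0.05).
#' @param repeats Number of random hold-outs (default 100).
#' @param trait,covariates Trait and covariate columns.
#' @param pcs Optional `pca_basis` or loadings matrix (rows must cover
#'   the cohort) used as additional covariates.
#' @param seed Integer seed.
#' @return An object of class `validation_result` with the per-repeat
#'   values and their summaries.
#' @export
holdout_validate <- function(model, genotypes, phenotypes, fraction = 0.05,
                             repeats = 100, trait = "height_cm",
                             covariates = c("sex", "age_years"), pcs = NULL,
                             seed = 1) {
  .check_fraction(fraction, "fraction", 0, 1, lo_open = TRUE, hi_open = TRUE)
  repeats <- .check_count(repeats, "repeats")
  ids <- intersect(sample_ids(genotypes), phenotypes$sample_id)
  n <- length(ids)
  n_hold <- floor(fraction * n)
  probe <- .covariate_matrix(phenotypes, covariates, pcs, ids[1])
  if (n_hold < ncol(probe) + 3)
    stop(sprintf("hold-out of %d sample(s) is too small for %d covariate column(s)",
                 n_hold, ncol(probe)), call. = FALSE)
  prof_all <- prs_score(model, subset_genotypes(genotypes, samples = ids))
  set.seed(seed)
  r2_full <- inc <- r <- beta <- pval <- numeric(repeats)
  for (b in seq_len(repeats)) {
    hold <- sample(ids, n_hold)
    y <- as.numeric(phenotypes[[trait]][match(hold, phenotypes$sample_id)])
    X <- .covariate_matrix(phenotypes, covariates, pcs, hold)
    s <- prof_all$scaled_score[match(hold, prof_all$sample_id)]
    ok <- stats::complete.cases(cbind(y, X, s))
    fw <- .incremental_r2(y[ok], X[ok, , drop = FALSE],
                          matrix(s[ok], ncol = 1))
    r2_full[b] <- fw$r2_base + fw$inc[1]
    inc[b] <- fw$inc[1]
    r[b] <- if (stats::sd(s[ok]) == 0) 0 else stats::cor(s[ok], y[ok])
    # coefficient of the scaled score in the full model, via FWL
    ss_s <- sum(fw$St^2)
    beta[b] <- if (ss_s > 0) sum(fw$St * fw$yt) / ss_s else 0
    rp <- fw$partial_r[1]
    tt <- rp * sqrt(fw$df / max(1 - rp^2, 1e-300))
    pval[b] <- 2 * stats::pt(-abs(tt), fw$df)
  }
  structure(list(fraction = fraction, repeats = repeats,
                 r2_full = r2_full, incremental_r2 = inc, pearson_r = r,
                 beta_scaled = beta, beta_p = pval,
                 mean_r2 = mean(r2_full), sd_r2 = stats::sd(r2_full),
                 mean_incremental_r2 = mean(inc),
                 sd_incremental_r2 = stats::sd(inc),
                 mean_r = mean(r, na.rm = TRUE),
                 mean_beta = mean(beta), median_beta_p = stats::median(pval)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("holdout validation (%d repeats, %.0f%% left out):\n",
              x$repeats, 100 * x$fraction))
  cat(sprintf("  full-model R2: %.4f +/- %.4f\n", x$mean_r2, x$sd_r2))
  cat(sprintf("  incremental R2: %.4f +/- %.4f\n", x$mean_incremental_r2,
              x$sd_incremental_r2))
  cat(sprintf("  PRS-trait Pearson r: %.4f\n", x$mean_r))
  cat(sprintf("  scaled-PRS coefficient: %.3f (median p %s)\n", x$mean_beta,
              format(x$median_beta_p, digits = 3)))
  invisible(x)
}

#' Pooled or Welch two-sample t-test from summary statistics
#'
#' Closed-form independent-samples t-test from group means, SDs and
#' sizes, as used for descriptive tables. The difference is reported as
#' `mean2 - mean1`.
#'
#' @param mean1,sd1,n1 First group (e.g. females).
#' @param mean2,sd2,n2 Second group (e.g. males).
#' @param var_equal Pooled-variance test when `TRUE` (default), Welch
#'   otherwise.
#' @return List with `difference`, `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               var_equal = TRUE) {
  diff <- mean2 - mean1
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  t <- diff / se
  list(difference = diff, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Sex-stratified descriptive statistics
#'
#' Per continuous variable: group means and SDs, the group-2 minus
#' group-1 difference and an independent-samples t-test (pooled variance
#' by default). Binary variables are summarised as percentages with a
#' chi-square test. Groups with fewer than 2 observations cause the
#' variable to be skipped with a warning.
#'
#' @param ph Phenotype table.
#' @param group Grouping column (default `"sex"`); its first two levels
#'   define group 1 and group 2.
#' @param variables Continuous columns to describe.
#' @param binary Binary (0/1) columns to describe as proportions.
#' @param var_equal Pooled-variance t-test when `TRUE` (default).
#' @return Data frame of class `descriptives` with one row per variable:
#'   `variable, group1, group2, mean1, sd1, mean2, sd2, difference,
#'   statistic, p, type`.
#' @export
cohort_descriptives <- function(ph, group = "sex",
                                variables = c("age_years", "weight_kg",
                                              "height_cm", "bmi",
                                              "sbp", "dbp"),
                                binary = "antihtn", var_equal = TRUE) {
  if (!group %in% names(ph)) stop("grouping column '", group, "' not found", call. = FALSE)
  gvar <- factor(ph[[group]])
  lev <- levels(gvar)[1:2]
  rows <- list()
  for (v in intersect(variables, names(ph))) {
    x1 <- ph[[v]][gvar == lev[1]]
    x2 <- ph[[v]][gvar == lev[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) {
      warning("variable '", v, "' skipped: a group has fewer than 2 observations")
      next
    }
    tt <- ttest_from_summary(mean(x1), stats::sd(x1), length(x1),
                             mean(x2), stats::sd(x2), length(x2),
                             var_equal = var_equal)
    rows[[v]] <- data.frame(variable = v, group1 = lev[1], group2 = lev[2],
                            mean1 = mean(x1), sd1 = stats::sd(x1),
                            mean2 = mean(x2), sd2 = stats::sd(x2),
                            difference = tt$difference, statistic = tt$t,
                            p = tt$p, type = "continuous",
                            stringsAsFactors = FALSE)
  }
  for (v in intersect(binary, names(ph))) {
    x1 <- ph[[v]][gvar == lev[1]]
    x2 <- ph[[v]][gvar == lev[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) {
      warning("variable '", v, "' skipped: a group has fewer than 2 observations")
      next
    }
    tab <- rbind(c(sum(x1 == 1), sum(x1 == 0)),
                 c(sum(x2 == 1), sum(x2 == 0)))
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p1 <- 100 * mean(x1 == 1); p2 <- 100 * mean(x2 == 1)
    rows[[v]] <- data.frame(variable = v, group1 = lev[1], group2 = lev[2],
                            mean1 = p1, sd1 = NA_real_,
                            mean2 = p2, sd2 = NA_real_,
                            difference = p2 - p1,
                            statistic = unname(ch$statistic),
                            p = ch$p.value, type = "binary (%)",
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    out <- data.frame(variable = character(0), group1 = character(0),
                      group2 = character(0), mean1 = numeric(0),
                      sd1 = numeric(0), mean2 = numeric(0), sd2 = numeric(0),
                      difference = numeric(0), statistic = numeric(0),
                      p = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("descriptives", "data.frame")
  out
}

#' Association of a PRS with a secondary phenotype
#'
#' For each covariate set, ordinary least squares of the outcome on the
#' min-max-scaled PRS plus the covariates; the unadjusted Pearson
#' correlation between the scaled score and the outcome is attached as
#' attributes `"pearson_r"` / `"pearson_p"`.
#'
#' @param profile A `prs_profile` (see [prs_score()]).
#' @param ph Phenotype table.
#' @param outcome Outcome column (default `"dbp"`).
#' @param covariate_sets Named list of covariate-column vectors; the
#'   defaults mirror a blood-pressure analysis (model 1: age, sex, BMI;
#'   model 2: plus antihypertensive-medication use).
#' @return Data frame with one row per model: `model, beta, se, t, p, n`.
#' @export
secondary_association <- function(profile, ph, outcome = "dbp",
                                  covariate_sets = list(
                                    model1 = c("age_years", "sex", "bmi"),
                                    model2 = c("age_years", "sex", "bmi",
                                               "antihtn"))) {
  ids <- intersect(profile$sample_id, ph$sample_id)
  y <- as.numeric(ph[[outcome]][match(ids, ph$sample_id)])
  if (stats::var(y, na.rm = TRUE) == 0)
    stop("outcome '", outcome, "' is constant", call. = FALSE)
  s <- profile$scaled_score[match(ids, profile$sample_id)]
  rows <- lapply(names(covariate_sets), function(nm) {
    X <- .covariate_matrix(ph, covariate_sets[[nm]], NULL, ids)
    ok <- stats::complete.cases(cbind(y, X, s))
    fit <- stats::lm.fit(cbind(X[ok, , drop = FALSE], prs = s[ok]), y[ok])
    k <- length(fit$coefficients)
    rss <- sum(fit$residuals^2)
    df <- sum(ok) - k
    XtXinv <- chol2inv(chol(crossprod(cbind(X[ok, , drop = FALSE], s[ok]))))
    se <- sqrt(rss / df * XtXinv[k, k])
    beta <- unname(fit$coefficients["prs"])
    tt <- beta / se
    data.frame(model = nm, beta = beta, se = se, t = tt,
               p = 2 * stats::pt(-abs(tt), df), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok0 <- stats::complete.cases(cbind(y, s))
  ct <- stats::cor.test(s[ok0], y[ok0])
  attr(out, "pearson_r") <- unname(ct$estimate)
  attr(out, "pearson_p") <- ct$p.value
  out
}

#' SNP-set overlap between PRS models
#'
#' Exact set intersection between the variants of a PRS model and an
#' external variant list (or second model). Duplicate identifiers are
#' deduplicated with a warning.
#'
#' @param model_a A [prs_model()] (or character vector of ids).
#' @param external A character vector of variant ids or a second
#'   [prs_model()].
#' @param key `"id"` intersects on variant identifiers; `"position"`
#'   intersects on a `chrom:pos` composite key (available when both
#'   sides are [prs_model()] objects), for sets whose id conventions
#'   differ.
#' @return List with `n_a`, `n_b`, `n_intersection`, and `fraction_a`
#'   (share of model A's variants in the intersection).
#' @export
prs_overlap <- function(model_a, external, key = c("id", "position")) {
  key <- match.arg(key)
  pick <- function(x) {
    if (inherits(x, "prs_model")) {
      if (key == "position") paste(x$entries$chrom, x$entries$pos, sep = ":")
      else x$entries$variant_id
    } else {
      if (key == "position")
        stop("'key = \"position\"' needs prs_model inputs on both sides",
             call. = FALSE)
      as.character(x)
    }
  }
  a <- pick(model_a)
  b <- pick(external)
  if (anyDuplicated(a)) { warning("duplicate ids in model A deduplicated"); a <- unique(a) }
  if (anyDuplicated(b)) { warning("duplicate ids in external set deduplicated"); b <- unique(b) }
  inter <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_intersection = inter,
       fraction_a = if (length(a)) inter / length(a) else NA_real_)
}
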