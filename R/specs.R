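#' @keywords internal
.check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", field), call. = FALSE)
  bad <- if (lo_open) x <= lo else x < lo
  bad <- bad || if (hi_open) x >= hi else x > hi
  if (bad)
    stop(sprintf("'%s' must be in %s%g, %g%s (got %g)", field,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]", x), call. = FALSE)
  x
}

.check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", field, min), call. = FALSE)
  as.integer(x)
}

#' Linkage-block layout for genotype simulation
#'
#' Describes the linkage-disequilibrium (LD) structure of a simulated
#' variant panel: variants come in blocks, and within a block all pairs
#' share a latent (Gaussian copula) correlation `within_block_rho`.
#' Variants in different blocks are independent.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size Variants per block.
#' @param within_block_rho Latent within-block correlation, in `[0, 1)`.
#'   The realised dosage correlation is attenuated relative to this latent
#'   value by the dichotomisation at the allele frequency.
#' @param maf_range Length-2 numeric, lower/upper bound for the ancestral
#'   allele frequency, each in `(0, 0.5]`.
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(n_blocks = 100, block_size = 50,
                          within_block_rho = 0.7, maf_range = c(0.05, 0.5)) {
  n_blocks <- .check_count(n_blocks, "n_blocks")
  block_size <- .check_count(block_size, "block_size")
  .check_fraction(within_block_rho, "within_block_rho", 0, 1, hi_open = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2L)
    stop("'maf_range' must be a length-2 numeric vector", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop("'maf_range' must satisfy 0 < low <= high <= 0.5", call. = FALSE)
  structure(list(n_blocks = n_blocks, block_size = block_size,
                 within_block_rho = within_block_rho, maf_range = maf_range),
            class = "ld_block_spec")
}

#' Population-structure layout for genotype simulation
#'
#' Subpopulation allele frequencies follow the Balding-Nichols model:
#' each subpopulation's frequency is Beta-distributed around the ancestral
#' frequency with differentiation governed by `fst`.
#'
#' @param n_subpops Number of subpopulations.
#' @param fst Differentiation parameter, in `[0, 0.2]`. Zero means an
#'   unstructured (panmictic) cohort.
#' @param mixing_weights Per-subpopulation sampling proportions, summing
#'   to 1; defaults to equal weights.
#' @return An object of class `structure_spec`.
#' @export
structure_spec <- function(n_subpops = 1, fst = 0, mixing_weights = NULL) {
  n_subpops <- .check_count(n_subpops, "n_subpops")
  .check_fraction(fst, "fst", 0, 0.2)
  if (is.null(mixing_weights)) mixing_weights <- rep(1 / n_subpops, n_subpops)
  if (length(mixing_weights) != n_subpops || any(mixing_weights < 0))
    stop("'mixing_weights' must be non-negative with one entry per subpopulation",
         call. = FALSE)
  if (abs(sum(mixing_weights) - 1) > 1e-12)
    stop("'mixing_weights' must sum to 1", call. = FALSE)
  if (fst > 0 && n_subpops < 2)
    stop("'fst' > 0 requires 'n_subpops' >= 2", call. = FALSE)
  structure(list(n_subpops = n_subpops, fst = fst,
                 mixing_weights = mixing_weights),
            class = "structure_spec")
}

#' Additive trait architecture for phenotype simulation
#'
#' @param n_causal Number of causal variants.
#' @param heritability Fraction of total trait variance attributable to the
#'   additive genetic value, in `[0, 1]`. Interpreted against the *total*
#'   trait variance, i.e. including the sex/age covariate contribution.
#' @param sex_effect Male-minus-female offset, trait units. The default
#'   mirrors the familiar ~12.7 cm adult-height sex gap.
#' @param age_slope Trait units per year of age.
#' @param effect_distribution Distribution of per-variant effects;
#'   only `"gaussian"` is implemented.
#' @param trait_sd Target total phenotypic standard deviation, trait units.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(n_causal = 200, heritability = 0.5,
                               sex_effect = 12.7, age_slope = -0.05,
                               effect_distribution = "gaussian",
                               trait_sd = 9.5) {
  n_causal <- .check_count(n_causal, "n_causal", min = 0)
  .check_fraction(heritability, "heritability", 0, 1)
  effect_distribution <- match.arg(effect_distribution, "gaussian")
  if (!is.numeric(trait_sd) || trait_sd <= 0)
    stop("'trait_sd' must be positive", call. = FALSE)
  structure(list(n_causal = n_causal, heritability = heritability,
                 sex_effect = sex_effect, age_slope = age_slope,
                 effect_distribution = effect_distribution,
                 trait_sd = trait_sd),
            class = "trait_architecture")
}

#' Quality-control thresholds
#'
#' Variants are removed when their imputation INFO score, call rate or
#' minor-allele frequency is *strictly below* the corresponding threshold;
#' samples are removed when their call rate is strictly below
#' `min_sample_callrate`.
#'
#' @param min_info Minimum imputation INFO score (default 0.9).
#' @param min_variant_callrate Minimum per-variant call rate (default 0.95).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @param min_sample_callrate Minimum per-sample call rate (default 0.90).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_info = 0.9, min_variant_callrate = 0.95,
                          min_maf = 0.05, min_sample_callrate = 0.90) {
  .check_fraction(min_info, "min_info")
  .check_fraction(min_variant_callrate, "min_variant_callrate")
  .check_fraction(min_maf, "min_maf")
  .check_fraction(min_sample_callrate, "min_sample_callrate")
  structure(list(min_info = min_info,
                 min_variant_callrate = min_variant_callrate,
                 min_maf = min_maf,
                 min_sample_callrate = min_sample_callrate),
            class = "qc_thresholds")
}

#' LD-pruning parameters
#'
#' @param window_kb Window size in kilobases; two variants are "within the
#'   window" when their positions differ by at most `window_kb` kb.
#' @param step Scan advance, in variants. The scan is carried out
#'   variant-by-variant (the strictest setting); the argument is retained
#'   for configuration compatibility and values other than 1 are accepted
#'   but do not change the result.
#' @param r2_threshold Maximum allowed squared correlation between two
#'   retained variants within the window (default 0.2).
#' @return An object of class `prune_params`.
#' @export
prune_params <- function(window_kb = 250, step = 1, r2_threshold = 0.2) {
  if (!is.numeric(window_kb) || window_kb <= 0)
    stop("'window_kb' must be positive", call. = FALSE)
  .check_count(step, "step")
  .check_fraction(r2_threshold, "r2_threshold", 0, 1, lo_open = TRUE)
  structure(list(window_kb = window_kb, step = step,
                 r2_threshold = r2_threshold),
            class = "prune_params")
}

#' Clumping-and-thresholding parameters
#'
#' @param clump_window_kb Clumping window in kilobases (default 250).
#' @param clump_r2 Squared-correlation threshold above which a variant is
#'   claimed by a more significant index variant (default 0.1).
#' @param p_grid Ascending grid of p-value inclusion thresholds scanned
#'   when picking the best-fitting score.
#' @param n_permutations Number of phenotype permutations for the
#'   empirical p-value of the best score (default 10000).
#' @return An object of class `ct_params`.
#' @export
ct_params <- function(clump_window_kb = 250, clump_r2 = 0.1,
                      p_grid = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                 0.1, 0.2, 0.3, 0.4, 0.5, 1.0),
                      n_permutations = 10000) {
  if (!is.numeric(clump_window_kb) || clump_window_kb <= 0)
    stop("'clump_window_kb' must be positive", call. = FALSE)
  .check_fraction(clump_r2, "clump_r2", 0, 1, lo_open = TRUE)
  if (!is.numeric(p_grid) || length(p_grid) < 1 || any(p_grid <= 0) ||
      any(p_grid > 1) || is.unsorted(p_grid, strictly = TRUE))
    stop("'p_grid' must be a strictly ascending vector of thresholds in (0, 1]",
         call. = FALSE)
  n_permutations <- .check_count(n_permutations, "n_permutations", min = 0)
  structure(list(clump_window_kb = clump_window_kb, clump_r2 = clump_r2,
                 p_grid = p_grid, n_permutations = n_permutations),
            class = "ct_params")
}
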