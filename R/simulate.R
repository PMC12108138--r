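#' Simulate a genotype dosage matrix with LD blocks and population structure
#'
#' Variants come in independent LD blocks; within a block, haplotypes are
#' generated from an exchangeable latent-Gaussian copula with correlation
#' `ld$within_block_rho`, thresholded at the (subpopulation-specific)
#' allele frequency, and the two haplotypes are summed to a 0/1/2 dosage.
#' Subpopulation allele frequencies follow the Balding-Nichols model:
#' `p_k ~ Beta(p0 (1 - F)/F, (1 - p0)(1 - F)/F)` around the ancestral
#' frequency `p0`, with `F = structure$fst`.
#'
#' Positions place each block on chromosome 1 with 2 kb within-block
#' spacing and a 1 Mb gap between blocks, so default pruning/clumping
#' windows never straddle blocks.
#'
#' @param n_samples Number of samples (>= 2).
#' @param ld An [ld_block_spec()].
#' @param structure A [structure_spec()].
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [genotype_matrix()]; the subpopulation assignment is attached
#'   as attribute `"subpop"`.
#' @export
simulate_genotypes <- function(n_samples, ld = ld_block_spec(),
                               structure = structure_spec(), seed = 1) {
  if (!inherits(ld, "ld_block_spec")) stop("'ld' must be an ld_block_spec", call. = FALSE)
  if (!inherits(structure, "structure_spec")) stop("'structure' must be a structure_spec", call. = FALSE)
  n_samples <- .check_count(n_samples, "n_samples", min = 2)
  set.seed(seed)
  m <- ld$n_blocks * ld$block_size
  p0 <- stats::runif(m, ld$maf_range[1], ld$maf_range[2])
  K <- structure$n_subpops
  fst <- structure$fst
  pk <- if (fst > 0) {
    a <- p0 * (1 - fst) / fst
    b <- (1 - p0) * (1 - fst) / fst
    vapply(seq_len(K), function(k) stats::rbeta(m, a, b), numeric(m))
  } else {
    matrix(p0, m, K)
  }
  pk[] <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
  subpop <- sample.int(K, n_samples, replace = TRUE, prob = structure$mixing_weights)
  rho <- ld$within_block_rho
  thr <- stats::qnorm(pk)              # m x K threshold per variant/subpop
  dosage <- matrix(0, n_samples, m)
  bs <- ld$block_size
  for (b in seq_len(ld$n_blocks)) {
    cols <- ((b - 1L) * bs + 1L):(b * bs)
    for (h in 1:2) {
      u <- stats::rnorm(n_samples)                       # shared block factor
      eps <- matrix(stats::rnorm(n_samples * bs), n_samples, bs)
      z <- sqrt(rho) * u + sqrt(1 - rho) * eps
      hap <- z < t(thr[cols, subpop, drop = FALSE])      # n x bs
      dosage[, cols] <- dosage[, cols] + hap
    }
  }
  block <- rep(seq_len(ld$n_blocks), each = bs)
  within <- rep(seq_len(bs), ld$n_blocks)
  variants <- data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = "1",
    pos = (block - 1L) * 1000000L + (within - 1L) * 2000L + 1L,
    effect_allele = "A",
    other_allele = "G",
    info = 1,
    stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("sample%04d", seq_len(n_samples))
  g <- genotype_matrix(dosage, variants)
  attr(g, "subpop") <- subpop
  g
}

#' Simulate phenotypes on top of a genotype matrix
#'
#' The trait is built as
#' `intercept + sex_effect * male + age_slope * age + g + e`,
#' where `g` is the additive genetic value over `arch$n_causal` randomly
#' chosen causal variants with i.i.d. Gaussian effects on standardized
#' dosages, rescaled so that the sample variance of `g` equals
#' `heritability * trait_sd^2` exactly, and `e` is Gaussian noise sized so
#' that the total trait variance is `trait_sd^2` in expectation. The
#' heritability is therefore a fraction of *total* trait variance.
#'
#' A secondary phenotype (`dbp`, diastolic blood pressure) shares a
#' fraction `secondary_rho` of its residual standard deviation with the
#' standardized genetic value, emulating a genetically correlated trait;
#' `sbp` carries no genetic share. Body weight is derived from height and
#' an independent BMI draw; an antihypertensive-medication flag is
#' Bernoulli with sex-dependent rates (12.2% female, 38.2% male).
#'
#' @param g A [genotype_matrix()].
#' @param arch A [trait_architecture()].
#' @param secondary_rho Genetic correlation of the secondary phenotype
#'   with the genetic value, in `[-1, 1]`.
#' @param seed Integer seed.
#' @param age_range Uniform age range in years.
#' @return A data frame (class `phenotype_table`) with columns
#'   `sample_id, height_cm, sex, age_years, weight_kg, bmi, sbp, dbp,
#'   antihtn`. The true genetic value and causal-effect table are attached
#'   as attributes `"true_genetic_value"` and `"causal"`.
#' @export
simulate_phenotypes <- function(g, arch = trait_architecture(),
                                secondary_rho = 0.3, seed = 1,
                                age_range = c(30, 80)) {
  if (!inherits(arch, "trait_architecture")) stop("'arch' must be a trait_architecture", call. = FALSE)
  .check_fraction(secondary_rho, "secondary_rho", -1, 1)
  n <- nrow(g$dosage)
  m <- ncol(g$dosage)
  if (arch$n_causal > m)
    stop(sprintf("'n_causal' (%d) exceeds the number of variants (%d)",
                 arch$n_causal, m), call. = FALSE)
  set.seed(seed)
  sex <- factor(ifelse(stats::runif(n) < 0.5, "female", "male"),
                levels = c("female", "male"))
  age <- stats::runif(n, age_range[1], age_range[2])

  causal_idx <- sort(sample.int(m, arch$n_causal))
  h2 <- arch$heritability
  sigma2 <- arch$trait_sd^2
  gv <- numeric(n)
  beta_std <- numeric(arch$n_causal)
  sd_c <- rep(1, arch$n_causal)
  if (arch$n_causal > 0 && h2 > 0) {
    Z <- standardize_dosage(subset_genotypes(g, variants = causal_idx), "unit")
    sd_c <- apply(g$dosage[, causal_idx, drop = FALSE], 2,
                  stats::sd, na.rm = TRUE)
    beta_raw <- stats::rnorm(arch$n_causal)
    gv_raw <- drop(Z %*% beta_raw)
    v <- stats::var(gv_raw)
    if (v <= 0) stop("degenerate genetic value (all causal variants monomorphic?)", call. = FALSE)
    sc <- sqrt(h2 * sigma2 / v)
    beta_std <- beta_raw * sc
    gv <- gv_raw * sc
  }
  male <- as.numeric(sex == "male")
  cov_part <- arch$sex_effect * male + arch$age_slope * age
  noise_var <- sigma2 * (1 - h2) - stats::var(cov_part)
  if (noise_var <= 0)
    stop("covariate variance plus heritability exceeds 'trait_sd^2'; ",
         "increase 'trait_sd' or lower 'heritability'", call. = FALSE)
  intercept <- 161.47 - arch$age_slope * mean(age_range)
  height <- intercept + cov_part + gv + stats::rnorm(n, 0, sqrt(noise_var))

  bmi <- 27.57 + 0.52 * male + stats::rnorm(n, 0, 4.8)
  bmi <- pmax(bmi, 15)
  weight <- bmi * (height / 100)^2
  sbp <- 123.65 + 8.6 * male + 0.30 * (age - mean(age_range)) +
    stats::rnorm(n, 0, 15)
  dbp_resid_sd <- 10
  g_std <- if (stats::sd(gv) > 0) (gv - mean(gv)) / stats::sd(gv) else numeric(n)
  dbp <- 75.31 + 5.7 * male + 0.15 * (age - mean(age_range)) +
    0.2 * (bmi - 27.8) +
    secondary_rho * dbp_resid_sd * g_std +
    sqrt(1 - secondary_rho^2) * dbp_resid_sd * stats::rnorm(n)
  antihtn <- stats::rbinom(n, 1, ifelse(male == 1, 0.382, 0.122))

  ph <- data.frame(sample_id = rownames(g$dosage), height_cm = height,
                   sex = sex, age_years = age, weight_kg = weight,
                   bmi = bmi, sbp = sbp, dbp = dbp, antihtn = antihtn,
                   stringsAsFactors = FALSE)
  class(ph) <- c("phenotype_table", "data.frame")
  attr(ph, "true_genetic_value") <- gv
  attr(ph, "causal") <- data.frame(
    id = g$variants$id[causal_idx],
    beta_std = beta_std,
    beta_dosage = ifelse(sd_c > 0, beta_std / sd_c, 0),
    stringsAsFactors = FALSE)
  ph
}

#' Degrade a genotype matrix with missingness and imputation-quality scores
#'
#' Injects per-entry missingness at rate `missing_rate`, attaches
#' per-variant INFO scores drawn uniformly from `info_dist` (when given),
#' and forces a designated fraction of samples below a 0.90 call rate
#' (12% of their genotypes set missing), producing inputs that exercise
#' every QC rule. With all rates zero and `info_dist = NULL` the input is
#' returned unchanged.
#'
#' @param g A [genotype_matrix()].
#' @param missing_rate Per-entry missingness probability in `[0, 1]`.
#' @param info_dist `NULL` (keep existing INFO) or a length-2 numeric
#'   `(low, high)` range for uniform INFO scores.
#' @param bad_sample_fraction Fraction of samples forced below a 0.90
#'   call rate.
#' @param seed Integer seed.
#' @return A [genotype_matrix()]; ids of the engineered low-call-rate
#'   samples are attached as attribute `"bad_samples"`.
#' @export
degrade <- function(g, missing_rate = 0, info_dist = NULL,
                    bad_sample_fraction = 0, seed = 1) {
  .check_fraction(missing_rate, "missing_rate")
  .check_fraction(bad_sample_fraction, "bad_sample_fraction")
  if (!is.null(info_dist)) {
    if (!is.numeric(info_dist) || length(info_dist) != 2L ||
        info_dist[1] > info_dist[2] || info_dist[1] < 0 || info_dist[2] > 1)
      stop("'info_dist' must be a (low, high) pair within [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  d <- g$dosage
  v <- g$variants
  n <- nrow(d); m <- ncol(d)
  if (missing_rate > 0) {
    mask <- stats::runif(n * m) < missing_rate
    d[mask] <- NA_real_
  }
  bad <- character(0)
  if (bad_sample_fraction > 0) {
    n_bad <- round(bad_sample_fraction * n)
    if (n_bad > 0) {
      rows <- sample.int(n, n_bad)
      k <- ceiling(0.12 * m)
      for (r in rows) d[r, sample.int(m, k)] <- NA_real_
      bad <- rownames(d)[rows]
    }
  }
  if (!is.null(info_dist)) v$info <- stats::runif(m, info_dist[1], info_dist[2])
  out <- genotype_matrix(d, v)
  attr(out, "subpop") <- attr(g, "subpop")
  attr(out, "bad_samples") <- bad
  out
}

#' Simulate a complete cohort with known ground truth
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_phenotypes()] and [degrade()]. Phenotypes are generated from
#' the clean genotypes; degradation (missingness, INFO scores, bad
#' samples) is applied afterwards so the stored genetic ground truth is
#' exact.
#'
#' @param n_samples Number of samples.
#' @param ld,structure,arch,secondary_rho See the component generators.
#' @param missing_rate,info_dist,bad_sample_fraction See [degrade()].
#' @param seed Integer master seed.
#' @return An object of class `simulated_cohort`: list with `genotypes`,
#'   `phenotypes`, `causal` (variant id, true effects), and
#'   `true_genetic_value`.
#' @export
simulate_cohort <- function(n_samples = 2000, ld = ld_block_spec(),
                            structure = structure_spec(),
                            arch = trait_architecture(),
                            secondary_rho = 0.3,
                            missing_rate = 0.02, info_dist = c(0.75, 1),
                            bad_sample_fraction = 0, seed = 1) {
  g <- simulate_genotypes(n_samples, ld, structure, seed = seed)
  ph <- simulate_phenotypes(g, arch, secondary_rho, seed = seed + 1L)
  g <- degrade(g, missing_rate, info_dist, bad_sample_fraction,
               seed = seed + 2L)
  structure(list(genotypes = g, phenotypes = ph,
                 causal = attr(ph, "causal"),
                 true_genetic_value = attr(ph, "true_genetic_value")),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated_cohort: %d samples, %d variants, %d causal\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              nrow(x$causal)))
  vr <- stats::var(x$true_genetic_value) / stats::var(x$phenotypes$height_cm)
  cat(sprintf("  realized genetic variance fraction: %.3f\n", vr))
  invisible(x)
}
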