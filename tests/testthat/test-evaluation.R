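test_that("identical groups give zero difference and p = 1", {
  ph <- data.frame(sample_id = paste0("s", 1:6),
                   height_cm = c(1, 2, 3, 1, 2, 3),
                   sex = factor(rep(c("female", "male"), each = 3),
                                levels = c("female", "male")))
  d <- cohort_descriptives(ph, variables = "height_cm", binary = character(0))
  expect_equal(d$difference, 0)
  expect_equal(d$p, 1)
})

test_that("printed descriptive summaries reproduce their arithmetic", {
  # height: female 161.47 +/- 6.81 (n 1158), male 174.21 +/- 7.32 (n 812)
  tt <- ttest_from_summary(161.47, 6.81, 1158, 174.21, 7.32, 812)
  expect_equal(tt$difference, 12.74)
  expect_lt(tt$p, 1e-200)
  expect_equal(ttest_from_summary(71.80, 13.79, 1158,
                                  85.31, 13.99, 812)$difference, 13.51)
  expect_equal(ttest_from_summary(27.57, 5.28, 1158,
                                  28.09, 4.17, 812)$difference, 0.52)
})

test_that("the pooled t-test matches the closed form on tiny groups", {
  x1 <- c(5.1, 4.9, 5.4, 5.0, 5.2)
  x2 <- c(5.9, 6.1, 5.7, 6.0, 6.3)
  ph <- data.frame(sample_id = paste0("s", 1:10), height_cm = c(x1, x2),
                   sex = factor(rep(c("female", "male"), each = 5),
                                levels = c("female", "male")))
  d <- cohort_descriptives(ph, variables = "height_cm", binary = character(0))
  ref <- t.test(x2, x1, var.equal = TRUE)
  expect_equal(d$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(d$p, ref$p.value, tolerance = 1e-12)
  expect_equal(d$difference, mean(x2) - mean(x1), tolerance = 1e-12)
})

test_that("binary variables are summarised as proportions with chi-square", {
  set.seed(1)
  ph <- data.frame(sample_id = paste0("s", 1:200),
                   sex = factor(rep(c("female", "male"), each = 100),
                                levels = c("female", "male")),
                   antihtn = c(rbinom(100, 1, 0.1), rbinom(100, 1, 0.4)))
  d <- cohort_descriptives(ph, variables = character(0))
  ref <- suppressWarnings(chisq.test(table(ph$sex, ph$antihtn),
                                     correct = FALSE))
  expect_equal(d$p, ref$p.value, tolerance = 1e-12)
  expect_equal(d$difference, d$mean2 - d$mean1)
})

test_that("a group that is too small is skipped with a warning", {
  ph <- data.frame(sample_id = paste0("s", 1:4),
                   height_cm = c(1, 2, 3, 4),
                   sex = factor(c("female", "male", "male", "male"),
                                levels = c("female", "male")))
  expect_warning(cohort_descriptives(ph, variables = "height_cm",
                                     binary = character(0)),
                 "fewer than 2")
})

test_that("a zero-weight model validates as pure noise on hold-outs", {
  co <- simulate_cohort(n_samples = 300,
                        ld = ld_block_spec(5, 20, within_block_rho = 0.3),
                        arch = trait_architecture(n_causal = 20,
                                                  heritability = 0.4),
                        missing_rate = 0, seed = 31)
  model <- prs_model(data.frame(variant_id = variant_ids(co$genotypes)[1:10],
                                chrom = "1",
                                pos = co$genotypes$variants$pos[1:10],
                                effect_allele = "A", weight = 0))
  val <- holdout_validate(model, co$genotypes, co$phenotypes,
                          fraction = 0.3, repeats = 20, seed = 32)
  expect_lt(abs(val$mean_incremental_r2), 0.05)
  expect_lt(abs(val$mean_r), 0.25)
})

test_that("the oracle causal model recovers the simulated heritability", {
  co <- simulate_cohort(n_samples = 2000,
                        ld = ld_block_spec(10, 30, within_block_rho = 0.3),
                        arch = trait_architecture(n_causal = 60,
                                                  heritability = 0.3),
                        missing_rate = 0, seed = 33)
  idx <- match(co$causal$id, variant_ids(co$genotypes))
  model <- prs_model(data.frame(variant_id = co$causal$id, chrom = "1",
                                pos = co$genotypes$variants$pos[idx],
                                effect_allele = "A",
                                weight = co$causal$beta_dosage))
  val <- holdout_validate(model, co$genotypes, co$phenotypes,
                          fraction = 0.25, repeats = 20, seed = 34)
  expect_lt(abs(val$mean_incremental_r2 - 0.3), 0.05)
})

test_that("larger hold-outs give more stable estimates", {
  co <- simulate_cohort(n_samples = 800,
                        ld = ld_block_spec(8, 25, within_block_rho = 0.3),
                        arch = trait_architecture(n_causal = 40,
                                                  heritability = 0.4),
                        missing_rate = 0, seed = 35)
  idx <- match(co$causal$id, variant_ids(co$genotypes))
  model <- prs_model(data.frame(variant_id = co$causal$id, chrom = "1",
                                pos = co$genotypes$variants$pos[idx],
                                effect_allele = "A",
                                weight = co$causal$beta_dosage))
  v05 <- holdout_validate(model, co$genotypes, co$phenotypes,
                          fraction = 0.05, repeats = 40, seed = 36)
  v50 <- holdout_validate(model, co$genotypes, co$phenotypes,
                          fraction = 0.5, repeats = 40, seed = 36)
  expect_lte(v50$sd_r2, v05$sd_r2)
  expect_lt(abs(v50$mean_r2 - v05$mean_r2), 0.05)
})

test_that("hold-outs smaller than the covariate count are rejected", {
  co <- simulate_cohort(n_samples = 100,
                        ld = ld_block_spec(2, 10, within_block_rho = 0),
                        arch = trait_architecture(n_causal = 5), seed = 37)
  model <- prs_model(data.frame(variant_id = variant_ids(co$genotypes)[1:3],
                                chrom = "1",
                                pos = co$genotypes$variants$pos[1:3],
                                effect_allele = "A", weight = 1))
  expect_error(holdout_validate(model, co$genotypes, co$phenotypes,
                                fraction = 0.02, repeats = 2, seed = 38),
               "too small")
})

test_that("secondary association is null without genetic sharing", {
  zs <- vapply(1:10, function(s) {
    co <- simulate_cohort(n_samples = 300,
                          ld = ld_block_spec(5, 20, within_block_rho = 0.3),
                          arch = trait_architecture(n_causal = 20,
                                                    heritability = 0.5),
                          secondary_rho = 0, missing_rate = 0,
                          seed = 900 + s)
    idx <- match(co$causal$id, variant_ids(co$genotypes))
    model <- prs_model(data.frame(variant_id = co$causal$id, chrom = "1",
                                  pos = co$genotypes$variants$pos[idx],
                                  effect_allele = "A",
                                  weight = co$causal$beta_dosage))
    prof <- prs_score(model, co$genotypes)
    sec <- secondary_association(prof, co$phenotypes)
    sec$t[sec$model == "model1"]
  }, numeric(1))
  expect_lt(mean(abs(zs)), 2)
})

test_that("genetic sharing yields a positive PRS-DBP effect", {
  betas <- vapply(1:10, function(s) {
    co <- simulate_cohort(n_samples = 400,
                          ld = ld_block_spec(5, 20, within_block_rho = 0.3),
                          arch = trait_architecture(n_causal = 20,
                                                    heritability = 0.5),
                          secondary_rho = 0.3, missing_rate = 0,
                          seed = 1100 + s)
    idx <- match(co$causal$id, variant_ids(co$genotypes))
    model <- prs_model(data.frame(variant_id = co$causal$id, chrom = "1",
                                  pos = co$genotypes$variants$pos[idx],
                                  effect_allele = "A",
                                  weight = co$causal$beta_dosage))
    prof <- prs_score(model, co$genotypes)
    sec <- secondary_association(prof, co$phenotypes)
    sec$beta[sec$model == "model2"]
  }, numeric(1))
  expect_gte(mean(betas > 0), 0.9)
})

test_that("an irrelevant covariate barely moves the association", {
  co <- simulate_cohort(n_samples = 400,
                        ld = ld_block_spec(5, 20, within_block_rho = 0.3),
                        arch = trait_architecture(n_causal = 20,
                                                  heritability = 0.5),
                        secondary_rho = 0.3, missing_rate = 0, seed = 39)
  idx <- match(co$causal$id, variant_ids(co$genotypes))
  model <- prs_model(data.frame(variant_id = co$causal$id, chrom = "1",
                                pos = co$genotypes$variants$pos[idx],
                                effect_allele = "A",
                                weight = co$causal$beta_dosage))
  prof <- prs_score(model, co$genotypes)
  ph <- co$phenotypes
  set.seed(40)
  ph$junk <- rnorm(nrow(ph))
  sec <- secondary_association(prof, ph, covariate_sets = list(
    base = c("age_years", "sex", "bmi"),
    plus = c("age_years", "sex", "bmi", "junk")))
  expect_lt(abs(sec$beta[1] - sec$beta[2]), sec$se[1])
})

test_that("SNP-set overlap is exact set arithmetic", {
  a <- paste0("v", 1:10)
  expect_equal(prs_overlap(a, a)$n_intersection, 10)
  expect_equal(prs_overlap(a, a)$fraction_a, 1)
  expect_equal(prs_overlap(a, paste0("w", 1:5))$n_intersection, 0)
  for (s in 1:25) {
    set.seed(s)
    x <- sample(paste0("v", 1:40), sample(5:30, 1))
    y <- sample(paste0("v", 1:40), sample(5:30, 1))
    o <- prs_overlap(x, y)
    expect_equal(o$n_intersection, length(intersect(x, y)))
    expect_equal(o$n_intersection, prs_overlap(y, x)$n_intersection)
    expect_equal(o$fraction_a, length(intersect(x, y)) / length(x))
  }
  expect_warning(prs_overlap(c("a", "a", "b"), "b"), "duplicate")
})

test_that("empirical p-values are never printed as literal zero", {
  expect_equal(format_empirical_p(0, 100), "< 0.01")
  expect_equal(format_empirical_p(0.03, 100), "0.03")
})

test_that("overlap can fall back to a chrom:pos composite key", {
  e1 <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
                   pos = c(100, 200), effect_allele = "A", weight = 1)
  e2 <- data.frame(variant_id = c("alt1", "alt2"), chrom = "1",
                   pos = c(200, 300), effect_allele = "A", weight = 1)
  m1 <- prs_model(e1); m2 <- prs_model(e2)
  expect_equal(prs_overlap(m1, m2)$n_intersection, 0)
  expect_equal(prs_overlap(m1, m2, key = "position")$n_intersection, 1)
  expect_error(prs_overlap(c("a"), m2, key = "position"), "both sides")
})
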