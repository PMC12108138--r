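test_that("clumping keeps the most significant variant of a correlated pair", {
  set.seed(1)
  x <- as.numeric(rbinom(200, 2, 0.4))
  d <- cbind(x, x)
  rownames(d) <- sprintf("s%03d", 1:200)
  g <- genotype_matrix(d, data.frame(id = c("a", "b"), chrom = "1",
                                     pos = c(1000, 2000),
                                     effect_allele = "A", other_allele = "G",
                                     info = 1))
  ss <- toy_summary_stats(g, beta = c(0.5, 0.4), p = c(1e-8, 1e-4))
  expect_identical(clump(ss, g), "a")
})

test_that("uncorrelated variants all survive clumping", {
  g <- toy_genotypes(400, 12, seed = 2, maf = c(0.3, 0.5))
  ss <- toy_summary_stats(g, beta = rnorm(12), p = runif(12))
  expect_setequal(clump(ss, g, ct_params(clump_r2 = 0.2)), variant_ids(g))
})

test_that("clumping matches the brute-force oracle on randomized panels", {
  for (s in 1:25) {
    g <- simulate_genotypes(120, ld_block_spec(5, 10, within_block_rho = 0.6),
                            seed = 4000 + s)
    set.seed(5000 + s)
    m <- ncol(g$dosage)
    ss <- toy_summary_stats(g, beta = rnorm(m), p = runif(m))
    params <- ct_params(clump_window_kb = 10, clump_r2 = 0.2)
    got <- clump(ss, g, params)
    want <- oracle_clump(ss, g, 10, 0.2)
    expect_identical(got, want)
    # p-monotone index choice: every removed variant has p >= some index p
    expect_gte(min(ss$p_value[match(got, ss$variant_id)]), min(ss$p_value))
    expect_true(all(got %in% ss$variant_id))
  }
})

test_that("scoring follows the average-per-observed-allele formula", {
  d <- matrix(c(2, 2), 1, 2)
  rownames(d) <- "s1"
  g <- genotype_matrix(d, data.frame(id = c("a", "b"), chrom = "1",
                                     pos = c(1, 2), effect_allele = "A",
                                     other_allele = "G", info = 1))
  model <- prs_model(data.frame(variant_id = c("a", "b"), chrom = "1",
                                pos = c(1, 2), effect_allele = "A",
                                weight = c(1, -1)))
  prof <- prs_score(model, g)
  expect_equal(prof$raw_score, 0)
  expect_equal(prof$n_alleles_observed, 4L)
})

test_that("an all-zero model gives zero raw scores and 0.5 scaled scores", {
  g <- toy_genotypes(15, 6, seed = 3)
  model <- prs_model(data.frame(variant_id = variant_ids(g), chrom = "1",
                                pos = g$variants$pos, effect_allele = "A",
                                weight = 0))
  prof <- prs_score(model, g)
  expect_true(all(prof$raw_score == 0))
  expect_true(all(prof$scaled_score == 0.5))
})

test_that("scoring matches a double-loop oracle, including flips and missing", {
  for (s in 1:20) {
    g <- toy_genotypes(5, 10, seed = 6000 + s, missing_rate = 0.15)
    set.seed(7000 + s)
    ea <- ifelse(runif(10) < 0.3, "G", "A")  # some flipped entries
    model <- prs_model(data.frame(variant_id = variant_ids(g), chrom = "1",
                                  pos = g$variants$pos, effect_allele = ea,
                                  weight = rnorm(10)))
    prof <- prs_score(model, g)
    expect_equal(prof$raw_score, oracle_score(model, g), tolerance = 1e-12)
    prof2 <- prs_score(model, g, average = FALSE)
    expect_equal(prof2$raw_score, oracle_score(model, g, average = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("scores are linear over disjoint model unions (plain-sum form)", {
  g <- toy_genotypes(12, 8, seed = 8)
  set.seed(9)
  w <- rnorm(8)
  entry <- function(idx) data.frame(variant_id = variant_ids(g)[idx],
                                    chrom = "1", pos = g$variants$pos[idx],
                                    effect_allele = "A", weight = w[idx])
  pa <- prs_score(prs_model(entry(1:3)), g, average = FALSE)$raw_score
  pb <- prs_score(prs_model(entry(4:8)), g, average = FALSE)$raw_score
  pu <- prs_score(prs_model(entry(1:8)), g, average = FALSE)$raw_score
  expect_equal(pu, pa + pb, tolerance = 1e-12)
  expect_equal(pu, oracle_score(prs_model(entry(1:8)), g, average = FALSE),
               tolerance = 1e-12)
})

test_that("allele flips with negated weights leave associations unchanged", {
  g <- toy_genotypes(100, 6, seed = 10, maf = c(0.2, 0.5))
  set.seed(11)
  w <- rnorm(6)
  y <- rnorm(100) + 0.5 * g$dosage[, 2]
  m1 <- prs_model(data.frame(variant_id = variant_ids(g), chrom = "1",
                             pos = g$variants$pos, effect_allele = "A",
                             weight = w))
  flip <- c(2, 5)
  ea <- rep("A", 6); ea[flip] <- "G"
  w2 <- w; w2[flip] <- -w[flip]
  m2 <- prs_model(data.frame(variant_id = variant_ids(g), chrom = "1",
                             pos = g$variants$pos, effect_allele = ea,
                             weight = w2))
  s1 <- prs_score(m1, g, average = FALSE)$raw_score
  s2 <- prs_score(m2, g, average = FALSE)$raw_score
  # shifted by a constant (2 * sum of negated weights), correlation intact
  expect_equal(diff(range((s1 - s2))), 0, tolerance = 1e-12)
  expect_equal(abs(cor(s1, y)), abs(cor(s2, y)), tolerance = 1e-12)
})

test_that("unmatchable model variants are dropped, many of them fatal", {
  g <- toy_genotypes(10, 4, seed = 12)
  model <- prs_model(data.frame(variant_id = c(variant_ids(g)[1:2], "zz", "xx"),
                                chrom = "1", pos = 1:4, effect_allele = "A",
                                weight = 1))
  expect_message(prof <- prs_score(model, g), "unmatchable")
  model_bad <- prs_model(data.frame(variant_id = c("q1", "q2", "q3",
                                                   variant_ids(g)[1]),
                                    chrom = "1", pos = 1:4,
                                    effect_allele = "A", weight = 1))
  expect_error(suppressMessages(prs_score(model_bad, g)), "half")
})

test_that("best-threshold PRS derivation recovers a strong single variant", {
  g <- toy_genotypes(500, 30, seed = 13, maf = c(0.3, 0.5))
  set.seed(15)
  causal <- 17
  g_src <- subset_genotypes(g, samples = 1:300)
  g_tgt <- subset_genotypes(g, samples = 301:500)
  # effect sized so the causal variant carries ~20% of trait variance
  yy <- 170 + 2.2 * g$dosage[, causal] + rnorm(500, 0, 3.1)
  ph <- data.frame(sample_id = sample_ids(g), height_cm = yy,
                   sex = factor(sample(c("female", "male"), 500, TRUE),
                                levels = c("female", "male")),
                   age_years = runif(500, 30, 80))
  ss <- gwas_scan(g_src, ph)
  fit <- derive_best_prs(ss, g_tgt, ph, params = ct_params(p_grid = 1,
                                                           n_permutations = 200),
                         seed = 16)
  expect_true("v0017" %in% fit$model$entries$variant_id)
  expect_lt(abs(fit$incremental_r2 - 0.2), 0.05)
  expect_lt(fit$empirical_p, 0.05)
})

test_that("permutation p-values are deterministic under a fixed seed", {
  g <- toy_genotypes(150, 20, seed = 17)
  set.seed(18)
  ph <- data.frame(sample_id = sample_ids(g),
                   height_cm = rnorm(150, 170, 7),
                   sex = factor(sample(c("female", "male"), 150, TRUE),
                                levels = c("female", "male")),
                   age_years = runif(150, 30, 80))
  ss <- gwas_scan(subset_genotypes(g, samples = 1:100), ph)
  tgt <- subset_genotypes(g, samples = 101:150)
  f1 <- derive_best_prs(ss, tgt, ph,
                        params = ct_params(n_permutations = 300), seed = 19)
  f2 <- derive_best_prs(ss, tgt, ph,
                        params = ct_params(n_permutations = 300), seed = 19)
  expect_identical(f1$empirical_p, f2$empirical_p)
  expect_identical(f1$model$entries, f2$model$entries)
})

test_that("derivation fails when no variant passes the loosest threshold", {
  g <- toy_genotypes(50, 5, seed = 20)
  ss <- toy_summary_stats(g, beta = rnorm(5), p = rep(0.9, 5))
  ph <- data.frame(sample_id = sample_ids(g), height_cm = rnorm(50, 170, 7),
                   sex = factor(rep(c("female", "male"), 25),
                                levels = c("female", "male")),
                   age_years = runif(50, 30, 80))
  expect_error(derive_best_prs(ss, g, ph,
                               params = ct_params(p_grid = c(1e-8, 1e-6))),
               "loosest")
})

test_that("strand-ambiguous variants are flagged and optionally dropped", {
  g <- toy_genotypes(10, 4, seed = 21)
  g$variants$other_allele <- c("G", "T", "G", "C")
  g$variants$effect_allele <- c("A", "A", "A", "G")  # v2 A/T, v4 G/C ambiguous
  model <- prs_model(data.frame(variant_id = variant_ids(g), chrom = "1",
                                pos = g$variants$pos,
                                effect_allele = g$variants$effect_allele,
                                weight = 1))
  expect_message(p1 <- prs_score(model, g), "2 strand-ambiguous")
  p2 <- suppressMessages(prs_score(model, g, drop_ambiguous = TRUE))
  expect_equal(p2$n_alleles_observed,
               as.integer(rowSums(!is.na(g$dosage[, c(1, 3)])) * 2),
               ignore_attr = TRUE)
})
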