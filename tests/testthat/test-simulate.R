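test_that("simulation is reproducible and dosages are well formed", {
  ld <- ld_block_spec(n_blocks = 5, block_size = 10, within_block_rho = 0.5)
  g1 <- simulate_genotypes(50, ld, seed = 7)
  g2 <- simulate_genotypes(50, ld, seed = 7)
  expect_identical(g1, g2)
  expect_true(all(g1$dosage %in% c(0, 1, 2)))
  expect_equal(dim(g1$dosage), c(50L, 50L))

  co1 <- simulate_cohort(n_samples = 60, ld = ld,
                         arch = trait_architecture(n_causal = 5),
                         missing_rate = 0.05, seed = 3)
  co2 <- simulate_cohort(n_samples = 60, ld = ld,
                         arch = trait_architecture(n_causal = 5),
                         missing_rate = 0.05, seed = 3)
  expect_identical(co1, co2)
})

test_that("empirical allele frequencies respect the requested range", {
  ld <- ld_block_spec(n_blocks = 10, block_size = 20,
                      within_block_rho = 0, maf_range = c(0.2, 0.4))
  g <- simulate_genotypes(800, ld, seed = 2)
  maf <- variant_maf(g)
  # ~3 binomial SEs of slack at the boundaries
  slack <- 3 * sqrt(0.4 * 0.6 / (2 * 800))
  expect_true(all(maf > 0.2 - slack & maf < 0.4 + slack))
})

test_that("within-block LD is controlled by the latent correlation", {
  n <- 400
  g0 <- simulate_genotypes(n, ld_block_spec(4, 10, within_block_rho = 0),
                           seed = 5)
  C <- cor(g0$dosage)
  block <- rep(1:4, each = 10)
  within <- outer(block, block, "==") & upper.tri(C)
  expect_lt(mean(C[within]^2), 3 / n)

  g7 <- simulate_genotypes(n, ld_block_spec(4, 10, within_block_rho = 0.7),
                           seed = 5)
  C7 <- cor(g7$dosage)
  between <- outer(block, block, "!=") & upper.tri(C7)
  expect_gt(mean(C7[within]^2), mean(C7[between]^2))
  expect_lt(mean(C7[between]^2), 3 / n)
})

test_that("two subpopulations separate on the leading eigenvector", {
  g <- simulate_genotypes(1000,
                          ld_block_spec(10, 30, within_block_rho = 0),
                          structure_spec(2, fst = 0.05), seed = 11)
  sub <- attr(g, "subpop")
  expect_equal(sort(unique(sub)), c(1L, 2L))
  # independent check: direct eigen-decomposition of the correlation of
  # centred dosages, no package PCA code
  d <- scale(g$dosage, scale = FALSE)
  ev <- eigen(tcrossprod(d), symmetric = TRUE)
  pc1 <- ev$vectors[, 1]
  expect_gt(abs(cor(pc1, as.numeric(sub == 1))), 0.5)
})

test_that("realized heritability matches the requested fraction", {
  ratios <- vapply(1:10, function(s) {
    co <- simulate_cohort(n_samples = 600,
                          ld = ld_block_spec(10, 30, within_block_rho = 0.5),
                          arch = trait_architecture(n_causal = 50,
                                                    heritability = 0.5),
                          missing_rate = 0, seed = 100 + s)
    var(co$true_genetic_value) / var(co$phenotypes$height_cm)
  }, numeric(1))
  expect_true(all(ratios > 0.4 & ratios < 0.6))
  expect_lt(abs(mean(ratios) - 0.5), 0.03)
})

test_that("a zero-heritability trait is unrelated to the genetic value", {
  tvals <- vapply(1:20, function(s) {
    g <- simulate_genotypes(150, ld_block_spec(4, 15, within_block_rho = 0),
                            seed = 200 + s)
    ph <- simulate_phenotypes(g, trait_architecture(n_causal = 20,
                                                    heritability = 0),
                              seed = 300 + s)
    gv <- attr(ph, "true_genetic_value")
    if (var(gv) == 0) return(0)  # effects are all zero by construction
    unname(summary(lm(ph$height_cm ~ gv))$coefficients[2, 3])
  }, numeric(1))
  expect_true(all(abs(tvals) < 3))
})

test_that("secondary phenotype shares genetics only when asked", {
  cors <- vapply(1:10, function(s) {
    g <- simulate_genotypes(300, ld_block_spec(5, 20, within_block_rho = 0),
                            seed = 400 + s)
    ph <- simulate_phenotypes(g, trait_architecture(n_causal = 30,
                                                    heritability = 0.5),
                              secondary_rho = 0, seed = 500 + s)
    cor(attr(ph, "true_genetic_value"), ph$dbp)
  }, numeric(1))
  # null: mean correlation within ~3 SEs of zero
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)) + 0.05)

  g <- simulate_genotypes(500, ld_block_spec(5, 20, within_block_rho = 0),
                          seed = 42)
  ph <- simulate_phenotypes(g, trait_architecture(n_causal = 30,
                                                  heritability = 0.5),
                            secondary_rho = 0.5, seed = 43)
  expect_gt(cor(attr(ph, "true_genetic_value"), ph$dbp), 0.2)
})

test_that("degrade injects exactly the requested defects", {
  g <- simulate_genotypes(100, ld_block_spec(4, 20, within_block_rho = 0.3),
                          seed = 1)
  g0 <- degrade(g)  # all rates zero, INFO kept: the data are untouched
  expect_identical(g0$dosage, g$dosage)
  expect_identical(g0$variants, g$variants)
  gd <- degrade(g, missing_rate = 0.02, seed = 2)
  expect_lt(abs(mean(is.na(gd$dosage)) - 0.02), 0.005)

  g2 <- simulate_genotypes(1000, ld_block_spec(4, 25, within_block_rho = 0),
                           seed = 3)
  gb <- degrade(g2, missing_rate = 0, bad_sample_fraction = 0.05, seed = 4)
  low <- sample_callrate(gb) < 0.90
  expect_equal(sum(low), 50L)
  expect_setequal(names(low)[low], attr(gb, "bad_samples"))
  gi <- degrade(g2, info_dist = c(0.6, 0.8), seed = 5)
  expect_true(all(gi$variants$info >= 0.6 & gi$variants$info <= 0.8))
})

test_that("parameter validation names the offending field", {
  expect_error(ld_block_spec(within_block_rho = 1), "within_block_rho")
  expect_error(ld_block_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(structure_spec(2, fst = 0.3), "fst")
  expect_error(structure_spec(2, 0.05, mixing_weights = c(0.5, 0.4)),
               "sum to 1")
  expect_error(trait_architecture(heritability = 1.2), "heritability")
  g <- simulate_genotypes(20, ld_block_spec(2, 5), seed = 1)
  expect_error(simulate_phenotypes(g, trait_architecture(n_causal = 100)),
               "n_causal")
  expect_error(degrade(g, missing_rate = 1.5), "missing_rate")
})
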