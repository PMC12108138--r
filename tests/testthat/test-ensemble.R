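# minimal fake iteration records for the aggregation operations
fake_records <- function(id_sets, weights = NULL) {
  lapply(seq_along(id_sets), function(i) {
    ids <- id_sets[[i]]
    w <- if (is.null(weights)) rep(1, length(ids)) else weights[[i]]
    list(iteration = i, source_ids = character(0), target_ids = character(0),
         model = prs_model(data.frame(variant_id = ids, chrom = "1",
                                      pos = seq_along(ids),
                                      effect_allele = "A", weight = w)),
         beta = stats::setNames(w, ids),
         incremental_r2 = 0.01 * i, empirical_p = 0.5, prs_p = 0.5)
  })
}

test_that("frequency aggregation counts once per iteration", {
  sets <- list(c("a", "b"), c("a", "c"), c("a", "b", "c"), "a")
  counts <- aggregate_frequencies(fake_records(sets))
  expect_equal(unname(counts["a"]), 4L)
  expect_equal(unname(counts["b"]), 2L)
  expect_equal(unname(counts["c"]), 2L)
  expect_false("zz" %in% names(counts))
})

test_that("frequency aggregation matches a brute-force recount", {
  for (s in 1:30) {
    set.seed(s)
    sets <- replicate(10, sample(paste0("v", 1:25), sample(3:12, 1)),
                      simplify = FALSE)
    counts <- aggregate_frequencies(fake_records(sets))
    want <- oracle_counts(sets)
    expect_setequal(names(counts), names(want))
    expect_equal(counts[names(want)], want)
  }
})

test_that("local-maxima narrowing matches its definition and an oracle", {
  got <- narrow_down(make_candidates(c(0.10, 0.06, 0.07, 0.05)))
  expect_equal(got$table$min_freq, c(1L, 3L))
  mono <- narrow_down(make_candidates(c(0.5, 0.4, 0.3, 0.2)))
  expect_equal(mono$table$min_freq, 1L)
  single <- narrow_down(make_candidates(0.3))
  expect_equal(nrow(single$table), 1L)
  for (s in 1:40) {
    set.seed(s)
    x <- round(runif(sample(2:12, 1)), 3)
    got <- narrow_down(make_candidates(x))
    expect_equal(got$table$min_freq, oracle_local_maxima(x))
  }
})

test_that("bootstrap p-values count baseline exceedances", {
  expect_equal(bootstrap_p(make_candidate(0.9), c(0.1, 0.2, 0.3)), 0)
  expect_equal(bootstrap_p(make_candidate(0.05), c(0.1, 0.2, 0.3)), 1)
  # hand enumeration: baseline {.1 .3 .5 .7}, candidate mean .4 -> 2/4
  expect_equal(bootstrap_p(make_candidate(0.4), c(0.1, 0.3, 0.5, 0.7)), 0.5)
  for (s in 1:30) {
    set.seed(s)
    base <- runif(17)
    m <- runif(1)
    expect_equal(bootstrap_p(make_candidate(m), base),
                 oracle_bootstrap_p(base, m))
  }
  # monotone non-increasing in the candidate mean
  base <- runif(50)
  ms <- sort(runif(20))
  ps <- vapply(ms, function(m) bootstrap_p(make_candidate(m), base), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("finalize assigns whole-cohort effects to an unchanged SNP set", {
  g <- toy_genotypes(30, 5, seed = 1)
  ss <- toy_summary_stats(g, beta = c(0.1, -0.2, 0.05, 0.3, -0.4),
                          p = rep(0.01, 5))
  cand <- make_candidate(0.1, snp_set = c("v0001", "v0002", "v0003"))
  model <- finalize_prs(cand, ss)
  expect_setequal(model$entries$variant_id, cand$snp_set)
  expect_equal(model$entries$weight[match(c("v0001", "v0002", "v0003"),
                                          model$entries$variant_id)],
               c(0.1, -0.2, 0.05))
  cand2 <- make_candidate(0.1, snp_set = c("v0001", "zz"))
  expect_warning(m2 <- finalize_prs(cand2, ss), "dropped")
  expect_equal(m2$n_snps, 1L)
  cand3 <- make_candidate(0.1, snp_set = c("q1", "q2"))
  expect_error(finalize_prs(cand3, ss), "no candidate variant")
})

test_that("the ensemble is reproducible, nests candidates, and records partitions", {
  co <- simulate_cohort(n_samples = 250,
                        ld = ld_block_spec(10, 20, within_block_rho = 0.6),
                        arch = trait_architecture(n_causal = 25,
                                                  heritability = 0.5),
                        missing_rate = 0.01, info_dist = c(0.92, 1), seed = 5)
  fv <- filter_variants(co$genotypes)
  fs <- filter_samples(fv$genotypes)
  run <- function() run_ensemble(fs$genotypes, co$phenotypes,
                                 n_iterations = 3,
                                 ct = ct_params(n_permutations = 50),
                                 seed = 21)
  e1 <- suppressMessages(run())
  e2 <- suppressMessages(run())
  expect_identical(e1$records, e2$records)
  expect_identical(e1$baseline_r2, e2$baseline_r2)
  for (r in e1$records) {
    expect_length(intersect(r$source_ids, r$target_ids), 0)
    expect_equal(length(r$source_ids), floor(0.8 * nrow(fs$genotypes$dosage)))
  }
  cands <- build_candidates(e1, min_freq = 1)
  sets <- lapply(cands$candidates, `[[`, "snp_set")
  if (length(sets) > 1)
    for (k in 2:length(sets)) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  counts <- aggregate_frequencies(e1)
  for (cc in cands$candidates)
    expect_setequal(cc$snp_set, names(counts)[counts >= cc$min_freq])
  # floor above the maximum appearance count leaves no candidates
  empty <- build_candidates(e1, min_freq = max(counts) + 1L)
  expect_length(empty$candidates, 0)
})
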