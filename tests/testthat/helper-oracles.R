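# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and base helpers (cor, solve, table)
# rather than the package's own code paths.

toy_genotypes <- function(n, m, seed = 1, maf = c(0.1, 0.5),
                          missing_rate = 0, chrom = NULL, pos = NULL,
                          info = 1) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m, byrow = FALSE)
  d <- matrix(as.numeric(d), n, m)
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  rownames(d) <- sprintf("s%03d", seq_len(n))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(d, data.frame(
    id = sprintf("v%04d", seq_len(m)), chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G", info = info,
    stringsAsFactors = FALSE))
}

toy_summary_stats <- function(g, beta, p) {
  out <- data.frame(variant_id = g$variants$id,
                    chromosome = g$variants$chrom,
                    base_pair_location = g$variants$pos,
                    effect_allele = g$variants$effect_allele,
                    other_allele = g$variants$other_allele,
                    beta = beta, standard_error = abs(beta) / 2 + 0.1,
                    p_value = p, n = nrow(g$dosage),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# mean-imputed dosage column
.imp <- function(x) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

oracle_filter_variants <- function(g, t) {
  keep <- logical(ncol(g$dosage))
  for (j in seq_len(ncol(g$dosage))) {
    x <- g$dosage[, j]
    info <- g$variants$info[j]
    cr <- mean(!is.na(x))
    p <- mean(x, na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    if (is.na(maf)) maf <- 0
    keep[j] <- info >= t$min_info && cr >= t$min_variant_callrate &&
      maf >= t$min_maf
  }
  g$variants$id[keep]
}

oracle_clump <- function(ss, ld_ref, window_kb, r2max) {
  ord <- order(ss$p_value, ss$base_pair_location, ss$variant_id)
  ss <- ss[ord, ]
  alive <- rep(TRUE, nrow(ss))
  index <- character(0)
  while (any(alive)) {
    i <- which(alive)[1]
    alive[i] <- FALSE
    index <- c(index, ss$variant_id[i])
    ci <- match(ss$variant_id[i], ld_ref$variants$id)
    if (is.na(ci)) next
    for (k in which(alive)) {
      ck <- match(ss$variant_id[k], ld_ref$variants$id)
      if (is.na(ck)) next
      if (ss$chromosome[k] != ss$chromosome[i]) next
      if (abs(ss$base_pair_location[k] - ss$base_pair_location[i]) >
          window_kb * 1000) next
      r <- suppressWarnings(cor(.imp(ld_ref$dosage[, ci]),
                                .imp(ld_ref$dosage[, ck])))
      if (!is.na(r) && r^2 > r2max) alive[k] <- FALSE
    }
  }
  index
}

oracle_score <- function(model, g, average = TRUE) {
  n <- nrow(g$dosage)
  raw <- numeric(n)
  obs <- integer(n)
  for (i in seq_len(n)) {
    for (k in seq_len(nrow(model$entries))) {
      id <- model$entries$variant_id[k]
      j <- match(id, g$variants$id)
      if (is.na(j)) next
      ga <- g$variants[j, ]
      if (ga$effect_allele == model$entries$effect_allele[k]) flip <- FALSE
      else if (ga$other_allele == model$entries$effect_allele[k]) flip <- TRUE
      else next
      d <- g$dosage[i, j]
      if (is.na(d)) {
        freq <- mean(g$dosage[, j], na.rm = TRUE) / 2
        d <- 2 * (if (flip) 1 - freq else freq)
      } else {
        if (flip) d <- 2 - d
        obs[i] <- obs[i] + 1L
      }
      raw[i] <- raw[i] + model$entries$weight[k] * d
    }
  }
  if (average) raw <- ifelse(obs > 0, raw / (2 * obs), 0)
  raw
}

oracle_ols <- function(y, X, gcol) {
  ok <- !is.na(gcol)
  A <- cbind(gcol[ok], X[ok, , drop = FALSE])
  ct <- solve(t(A) %*% A, t(A) %*% y[ok])
  res <- y[ok] - A %*% ct
  df <- sum(ok) - ncol(A)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(t(A) %*% A)[1, 1])
  tt <- ct[1] / se
  list(beta = ct[1], se = se, p = 2 * pt(-abs(tt), df))
}

oracle_counts <- function(id_sets) {
  all <- unlist(lapply(id_sets, unique))
  tab <- table(all)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

oracle_local_maxima <- function(x) {
  out <- integer(0)
  for (i in seq_along(x)) {
    left_ok <- i == 1 || x[i] > x[i - 1]
    right_ok <- i == length(x) || x[i] > x[i + 1]
    if (left_ok && right_ok) out <- c(out, i)
  }
  out
}

oracle_bootstrap_p <- function(baseline, m) {
  cnt <- 0
  for (b in baseline) if (b > m) cnt <- cnt + 1
  cnt / length(baseline)
}

make_candidate <- function(mean_r2, min_freq = 10L, snp_set = "v1",
                           r2 = mean_r2) {
  structure(list(min_freq = as.integer(min_freq), snp_set = snp_set,
                 r2 = r2, mean_r2 = mean_r2, sd_r2 = stats::sd(r2),
                 n_snps = length(snp_set)),
            class = "candidate_prs")
}

make_candidates <- function(means, min_freqs = seq_along(means)) {
  cands <- Map(make_candidate, means, min_freqs)
  structure(list(candidates = cands,
                 table = data.frame(min_freq = as.integer(min_freqs),
                                    n_snps = 1L, mean_r2 = means,
                                    sd_r2 = NA_real_)),
            class = "prs_candidates")
}
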