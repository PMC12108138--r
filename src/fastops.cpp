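// Hot-path helpers shared by QC, pruning, PCA and scoring: one-pass
// column statistics, mean-imputed standardization, and the greedy
// windowed LD prune.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// callrate, mean (na.rm) and variance (na.rm) per column, one pass
// [[Rcpp::export(name = ".col_stats_cpp")]]
List col_stats_cpp(NumericMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  NumericVector callrate(m), mean(m), var(m);
  for (int j = 0; j < m; ++j) {
    const double* g = &G(0, j);
    double s = 0, s2 = 0; int k = 0;
    for (int i = 0; i < n; ++i) {
      double v = g[i];
      if (!ISNAN(v)) { s += v; s2 += v * v; ++k; }
    }
    callrate[j] = n > 0 ? (double)k / n : 0.0;
    mean[j] = k > 0 ? s / k : NA_REAL;
    var[j] = k > 1 ? (s2 - s * s / k) / (k - 1) : NA_REAL;
  }
  return List::create(_["callrate"] = callrate, _["mean"] = mean,
                      _["var"] = var);
}

// row call rates
// [[Rcpp::export(name = ".row_callrate_cpp")]]
NumericVector row_callrate_cpp(NumericMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  IntegerVector k(n);
  for (int j = 0; j < m; ++j) {
    const double* g = &G(0, j);
    for (int i = 0; i < n; ++i) if (!ISNAN(g[i])) ++k[i];
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = m > 0 ? (double)k[i] / m : 0.0;
  return out;
}

// mean-imputed standardization; patterson = centre at 2p, divide by
// sqrt(2p(1-p)); otherwise centre at the column mean, divide by the
// sample sd of the mean-imputed column (so pairwise correlations of the
// result are plain cross-products over n - 1). Zero-variance columns
// come back as all zeros.
// [[Rcpp::export(name = ".standardize_cpp")]]
NumericMatrix standardize_cpp(NumericMatrix G, bool patterson) {
  const int n = G.nrow(), m = G.ncol();
  NumericMatrix Z(n, m);
  for (int j = 0; j < m; ++j) {
    const double* g = &G(0, j);
    double s = 0, s2 = 0; int k = 0;
    for (int i = 0; i < n; ++i) {
      double v = g[i];
      if (!ISNAN(v)) { s += v; s2 += v * v; ++k; }
    }
    double mu = k > 0 ? s / k : 0.0;
    double sd;
    if (patterson) {
      double p = mu / 2.0;
      sd = std::sqrt(2.0 * p * (1.0 - p));
    } else {
      sd = (k > 1 && n > 1) ? std::sqrt((s2 - s * s / k) / (n - 1)) : 0.0;
    }
    double* z = &Z(0, j);
    if (sd < 1e-12) {
      for (int i = 0; i < n; ++i) z[i] = 0.0;
    } else {
      for (int i = 0; i < n; ++i) {
        double v = g[i];
        z[i] = ISNAN(v) ? 0.0 : (v - mu) / sd;
      }
    }
  }
  return Z;
}

// Greedy left-to-right windowed prune on standardized columns (assumed
// position-sorted within chromosome). Keeps column j unless some kept
// column on the same chromosome within window_bp has r^2 > r2max.
// [[Rcpp::export(name = ".prune_cpp")]]
LogicalVector prune_cpp(NumericMatrix Z, NumericVector pos,
                        IntegerVector chrom, double window_bp,
                        double r2max) {
  const int n = Z.nrow(), m = Z.ncol();
  LogicalVector keep(m);
  std::vector<int> kept;
  kept.reserve(m);
  const double denom = n > 1 ? (double)(n - 1) : 1.0;
  for (int j = 0; j < m; ++j) {
    bool ok = true;
    const double* zj = &Z(0, j);
    for (int t = (int)kept.size() - 1; t >= 0; --t) {
      int i = kept[t];
      if (chrom[i] != chrom[j]) break;
      if (pos[j] - pos[i] > window_bp) break;
      const double* zi = &Z(0, i);
      double dot = 0;
      for (int r = 0; r < n; ++r) dot += zi[r] * zj[r];
      double rr = dot / denom;
      if (rr * rr > r2max) { ok = false; break; }
    }
    if (ok) {
      keep[j] = true;
      kept.push_back(j);
    }
  }
  return keep;
}
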