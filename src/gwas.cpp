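// Per-variant ordinary least squares with exact per-variant dropping of
// samples whose dosage is missing.  Cross-products of the dosage with
// the covariates are computed in one BLAS pass over the zero-filled
// dosage matrix; for variant j the covariate cross-product matrix over
// the retained samples is then obtained by downdating the full-cohort
// X'X, X'y and y'y by the (few) rows in the missing set, so the scan is
// O(n p) BLAS work per variant plus O(|missing| p^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".gwas_ols_cpp")]]
List gwas_ols_cpp(NumericMatrix Gin, arma::mat X, arma::vec y) {
  const int n = Gin.nrow(), m = Gin.ncol(), p = X.n_cols;
  arma::mat G0(n, m);
  std::vector<std::vector<int>> miss(m);
  for (int j = 0; j < m; ++j) {
    const double* g = &Gin(0, j);
    double* z = G0.colptr(j);
    for (int i = 0; i < n; ++i) {
      double v = g[i];
      if (ISNAN(v)) { z[i] = 0.0; miss[j].push_back(i); }
      else z[i] = v;
    }
  }
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  const double yty = arma::dot(y, y);
  arma::mat GX = G0.t() * X;                    // m x p
  arma::vec Gy = G0.t() * y;                    // m
  arma::rowvec Gg = arma::sum(arma::square(G0), 0);
  arma::vec ones(n, arma::fill::ones);
  arma::vec Gsum = G0.t() * ones;

  NumericVector beta(m), se(m), df(m), nused(m);
  arma::mat A(p + 1, p + 1), Am(p, p), L;
  arma::vec b(p + 1), bm(p), sol(p + 1), e0(p + 1);

  for (int j = 0; j < m; ++j) {
    Am = XtX;
    bm = Xty;
    double yym = yty;
    int nj = n - (int)miss[j].size();
    for (int idx : miss[j]) {
      arma::rowvec xi = X.row(idx);
      Am -= xi.t() * xi;
      bm -= xi.t() * y(idx);
      yym -= y(idx) * y(idx);
    }
    int dfj = nj - (p + 1);
    double varg = nj > 1 ? (Gg(j) - Gsum(j) * Gsum(j) / nj) / (nj - 1) : 0.0;
    if (dfj < 1 || varg <= 0.0) {
      beta[j] = NA_REAL; se[j] = NA_REAL; df[j] = dfj; nused[j] = nj;
      continue;
    }
    A(0, 0) = Gg(j);
    for (int k = 0; k < p; ++k) { A(0, k + 1) = GX(j, k); A(k + 1, 0) = GX(j, k); }
    A.submat(1, 1, p, p) = Am;
    b(0) = Gy(j);
    b.subvec(1, p) = bm;
    bool ok = arma::chol(L, A, "lower");
    if (!ok) { beta[j] = NA_REAL; se[j] = NA_REAL; df[j] = dfj; nused[j] = nj; continue; }
    sol = arma::solve(arma::trimatu(L.t()),
                      arma::solve(arma::trimatl(L), b));
    e0.zeros(); e0(0) = 1.0;
    arma::vec inv0 = arma::solve(arma::trimatu(L.t()),
                                 arma::solve(arma::trimatl(L), e0));
    double rss = yym - arma::dot(sol, b);
    if (rss < 0) rss = 0;
    double sigma2 = rss / dfj;
    beta[j] = sol(0);
    se[j] = std::sqrt(sigma2 * inv0(0));
    df[j] = dfj;
    nused[j] = nj;
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["df"] = df, _["n"] = nused);
}
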