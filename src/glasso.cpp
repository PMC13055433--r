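// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double softThresh(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Friedman-style block coordinate descent graphical lasso, used only as a
// thin comparator (sparse inverse covariance on CLR-transformed data).
// Returns the working covariance W and the regression coefficient matrix B
// (column j holds the lasso coefficients of feature j on the others); the
// off-diagonal support of the precision matrix equals the support of B.
// [[Rcpp::export]]
List glasso_fit(const arma::mat& S, double rho,
                Nullable<NumericMatrix> W0, Nullable<NumericMatrix> B0,
                int maxOuter, double tol, int maxInner) {
  const int p = S.n_rows;
  arma::mat W = W0.isNotNull() ? as<arma::mat>(W0.get())
                               : arma::mat(S + rho * arma::eye(p, p));
  arma::mat B = B0.isNotNull() ? as<arma::mat>(B0.get())
                               : arma::mat(p, p, arma::fill::zeros);
  const double offScale = arma::mean(arma::abs(
      S(arma::find(arma::trimatu(arma::ones<arma::mat>(p, p), 1))))) + 1e-12;

  bool converged = false;
  int outer = 0;
  for (outer = 1; outer <= maxOuter; ++outer) {
    double maxDiff = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso: min 1/2 b' W11 b - s12' b + rho |b|_1
      for (int inner = 0; inner < maxInner; ++inner) {
        double chg = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double z = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            z -= W(k, l) * B(l, j);
          }
          double bNew = softThresh(z, rho) / W(k, k);
          double d = bNew - B(k, j);
          if (d != 0.0) {
            B(k, j) = bNew;
            double ad = std::fabs(d);
            if (ad > chg) chg = ad;
          }
        }
        if (chg < 0.01 * tol) break;
      }
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > maxDiff) maxDiff = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (maxDiff < tol * offScale) { converged = true; break; }
  }

  return List::create(
    _["W"] = W, _["B"] = B,
    _["nIter"] = std::min(outer, maxOuter),
    _["converged"] = converged);
}
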