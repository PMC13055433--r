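#include <Rcpp.h>
using namespace Rcpp;

static inline double uPow(double x, double c) {
  // centered power transform (x^c - 1)/c, log at c = 0
  if (c == 0.0) return std::log(x);
  return (std::pow(x, c) - 1.0) / c;
}

// Pairwise Gibbs sweeps over parallel chains on the simplex, targeting the
// unnormalized density exp(-1/2 u_a' K u_a + eta' u_b) per chain (row).
// Each sweep redistributes mass within floor(p/2) disjoint random
// coordinate pairs; the univariate conditional over the pair fraction
// xi = x_j / (x_j + x_k) is drawn by griddy inverse-CDF on G logit-spaced
// midpoints (density weighted by the Jacobian xi (1 - xi), which
// resolves the boundary concentrations of log-type models) with uniform
// jitter within the selected logit bin. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix gibbs_simplex(NumericMatrix X0, NumericMatrix K,
                            NumericMatrix Eta, double a, double b,
                            int nSweeps, int G) {
  const int n = X0.nrow(), p = X0.ncol();
  NumericMatrix X = clone(X0);
  // U = u_a(X), V = U %*% K
  NumericMatrix U(n, p), V(n, p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) U(i, j) = uPow(X(i, j), a);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < p; ++l) {
      double s = 0.0;
      for (int m = 0; m < p; ++m) s += U(i, m) * K(m, l);
      V(i, l) = s;
    }

  std::vector<double> lp(G);
  std::vector<int> perm(p);
  const double T = 12.0;          // logit grid spans xi in ~[6e-6, 1-6e-6]
  const double step = 2.0 * T / G;
  std::vector<double> xiGrid(G), logJac(G);
  for (int gidx = 0; gidx < G; ++gidx) {
    double t = -T + (gidx + 0.5) * step;
    double xi = 1.0 / (1.0 + std::exp(-t));
    xiGrid[gidx] = xi;
    logJac[gidx] = std::log(xi) + std::log(1.0 - xi);
  }

  for (int sweep = 0; sweep < nSweeps; ++sweep) {
    for (int j = 0; j < p; ++j) perm[j] = j;
    for (int j = p - 1; j > 0; --j) { // Fisher-Yates with R RNG
      int k = (int)std::floor(unif_rand() * (j + 1));
      if (k > j) k = j;
      std::swap(perm[j], perm[k]);
    }
    for (int pr = 0; pr + 1 < p; pr += 2) {
      int j = perm[pr], k = perm[pr + 1];
      double Kjj = K(j, j), Kkk = K(k, k), Kjk = K(j, k);
      for (int i = 0; i < n; ++i) {
        double m = X(i, j) + X(i, k);
        if (m <= 0.0) continue;
        double rj = V(i, j) - Kjj * U(i, j) - Kjk * U(i, k);
        double rk = V(i, k) - Kjk * U(i, j) - Kkk * U(i, k);
        double ej = Eta(i, j), ek = Eta(i, k);
        double mx = R_NegInf;
        for (int gidx = 0; gidx < G; ++gidx) {
          double xi = xiGrid[gidx];
          double xj = m * xi, xk = m - xj;
          double uj = uPow(xj, a), uk = uPow(xk, a);
          double v = -0.5 * (Kjj * uj * uj + Kkk * uk * uk
                             + 2.0 * Kjk * uj * uk)
                     - (rj * uj + rk * uk) + logJac[gidx];
          if (b == a) v += ej * uj + ek * uk;
          else v += ej * uPow(xj, b) + ek * uPow(xk, b);
          lp[gidx] = v;
          if (v > mx) mx = v;
        }
        double tot = 0.0;
        for (int gidx = 0; gidx < G; ++gidx) {
          lp[gidx] = std::exp(lp[gidx] - mx);
          tot += lp[gidx];
        }
        double target = unif_rand() * tot, cum = 0.0;
        int sel = G - 1;
        for (int gidx = 0; gidx < G; ++gidx) {
          cum += lp[gidx];
          if (cum >= target) { sel = gidx; break; }
        }
        double t = -T + (sel + unif_rand()) * step;
        double xi = 1.0 / (1.0 + std::exp(-t));
        double xjn = m * xi, xkn = m - xjn;
        double duj = uPow(xjn, a) - U(i, j);
        double duk = uPow(xkn, a) - U(i, k);
        for (int l = 0; l < p; ++l)
          V(i, l) += duj * K(j, l) + duk * K(k, l);
        U(i, j) += duj; U(i, k) += duk;
        X(i, j) = xjn; X(i, k) = xkn;
      }
    }
  }
  return X;
}
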