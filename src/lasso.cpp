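#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for one gene row of the L1-penalized
// steady-state regression: min ||b - X a||^2 + lambda ||a||_1, passed in
// through the Gram matrix G = X'X and the correlation vector c0 = X'b.
// Converges when the largest coefficient change in a sweep is below tol.
// [[Rcpp::export(name = ".cdLassoRow")]]
NumericVector cdLassoRow(const NumericMatrix& G, const NumericVector& c0,
                         double lambda, double tol = 1e-8,
                         int maxit = 100000) {
  const int p = c0.size();
  NumericVector a(p), Ga(p);
  const double thr = lambda / 2.0;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = G(j, j);
      if (gjj <= 0.0) continue;
      const double rho = c0[j] - Ga[j] + gjj * a[j];
      double anew = 0.0;
      if (rho > thr) anew = (rho - thr) / gjj;
      else if (rho < -thr) anew = (rho + thr) / gjj;
      const double d = anew - a[j];
      if (d != 0.0) {
        for (int k = 0; k < p; ++k) Ga[k] += G(k, j) * d;
        a[j] = anew;
        const double ad = d < 0 ? -d : d;
        if (ad > delta) delta = ad;
      }
    }
    if (delta < tol) break;
  }
  return a;
}
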