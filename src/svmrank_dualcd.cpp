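#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM over pair
// difference vectors, no intercept. X is the pooled instance matrix
// (n x d, column-major); pairs index preferred/other instances (1-based).
// The sweep order is supplied per pass so all randomness stays on the R
// side (seeded there).
// [[Rcpp::export(name = ".svmrankDualCD")]]
List svmrankDualCD(NumericMatrix X, IntegerVector ip, IntegerVector io,
                   double C, IntegerMatrix order, double tol) {
  const int n = X.nrow(), d = X.ncol(), P = ip.size();
  const int passes = order.ncol();
  std::vector<double> w(d, 0.0);
  NumericVector alpha(P);
  const double *x = REAL(X);
  // transpose to d x n so each instance vector is contiguous
  std::vector<double> xt((size_t)n * d);
  for (int k = 0; k < d; ++k)
    for (int i = 0; i < n; ++i)
      xt[(size_t)i * d + k] = x[i + (size_t)n * k];
  // squared norms of the pair difference vectors
  std::vector<double> q(P);
  for (int p = 0; p < P; ++p) {
    const double *xi = &xt[(size_t)(ip[p] - 1) * d];
    const double *xj = &xt[(size_t)(io[p] - 1) * d];
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      const double dk = xi[k] - xj[k];
      s += dk * dk;
    }
    q[p] = s > 1e-12 ? s : 1e-12;
  }
  int passesUsed = 0;
  for (int pass = 0; pass < passes; ++pass) {
    double maxDelta = 0.0;
    for (int t = 0; t < P; ++t) {
      const int p = order(t, pass) - 1;
      const double *xi = &xt[(size_t)(ip[p] - 1) * d];
      const double *xj = &xt[(size_t)(io[p] - 1) * d];
      double s = 0.0;
      for (int k = 0; k < d; ++k)
        s += w[k] * (xi[k] - xj[k]);
      const double g = s - 1.0;
      double aNew = alpha[p] - g / q[p];
      if (aNew < 0.0) aNew = 0.0; else if (aNew > C) aNew = C;
      const double delta = aNew - alpha[p];
      if (delta != 0.0) {
        for (int k = 0; k < d; ++k)
          w[k] += delta * (xi[k] - xj[k]);
        alpha[p] = aNew;
        const double ad = delta < 0 ? -delta : delta;
        if (ad > maxDelta) maxDelta = ad;
      }
    }
    passesUsed = pass + 1;
    if (maxDelta < tol) break;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = alpha, _["passes"] = passesUsed);
}
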