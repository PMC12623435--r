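#include <Rcpp.h>
#include <cmath>

// Approximate entropy (Pincus): Phi_m(r) - Phi_{m+1}(r) with Chebyshev
// distance and self-matches included. One O(N^2) pass counts template
// matches for m and m+1 simultaneously.
// [[Rcpp::export]]
double apen_cpp(Rcpp::NumericVector x, int m, double r) {
  const int n = x.size();
  if (n <= m + 1) Rcpp::stop("series too short for embedding dimension");
  const int nm = n - m + 1;      // templates of length m
  const int nm1 = n - m;         // templates of length m + 1
  std::vector<double> cm(nm, 0.0), cm1(nm1, 0.0);
  const double *v = x.begin();

  for (int i = 0; i < nm; ++i) {
    cm[i] += 1.0;                               // self-match, m
    if (i < nm1) cm1[i] += 1.0;                 // self-match, m + 1
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(v[i + k] - v[j + k]);
        if (dk > d) d = dk;
        if (d > r) break;
      }
      if (d <= r) {
        cm[i] += 1.0;
        cm[j] += 1.0;
        if (i < nm1 && j < nm1) {
          double dk = std::fabs(v[i + m] - v[j + m]);
          double d1 = dk > d ? dk : d;
          if (d1 <= r) {
            cm1[i] += 1.0;
            cm1[j] += 1.0;
          }
        }
      }
    }
  }

  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i) phi_m += std::log(cm[i] / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i) phi_m1 += std::log(cm1[i] / nm1);
  phi_m1 /= nm1;
  return phi_m - phi_m1;
}
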