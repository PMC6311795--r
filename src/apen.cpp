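#include <Rcpp.h>
using namespace Rcpp;

// Mean log correlation sum for embedding dimension m (self-matches included,
// Chebyshev distance, tolerance r) -- the phi_m of approximate entropy.
static double apen_phi(const NumericVector& x, const int m, const double r) {
  const int n = x.size();
  const int nm = n - m + 1;
  if (nm < 1) Rcpp::stop("series too short for embedding dimension %d", m);
  double acc = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      if (d <= r) ++cnt;
    }
    acc += std::log(static_cast<double>(cnt) / nm);
  }
  return acc / nm;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  return apen_phi(x, m, r) - apen_phi(x, m + 1, r);
}
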