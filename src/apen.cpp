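#include <Rcpp.h>
using namespace Rcpp;

// Phi_m(r): mean over i of log of the fraction of m-templates within
// Chebyshev distance r of template i (self-match included).
static double phi(const NumericVector& x, int m, double r) {
  const int n = x.size();
  const int nt = n - m + 1;  // number of templates
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) ++cnt;
    }
    acc += std::log((double)cnt / nt);
  }
  return acc / nt;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  double a = phi(x, m, r) - phi(x, m + 1, r);
  return a;
}
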