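#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// xmin scan for the power-law tail cutoff.
// v: sorted ascending, strictly positive sample.
// Returns the smallest unique value whose tail {x >= xmin} passes the KS
// acceptance band sqrt(m) * D <= ksCritical with fitted alpha <= alphaMax;
// if none does, the rightmost candidate with tail size >= minTail.
// [[Rcpp::export(name = ".powerLawScan")]]
double powerLawScan(NumericVector v, int minTail, double ksCritical,
                    double alphaMax) {
  const int n = v.size();
  std::vector<double> logv(n), suffix(n + 1);
  for (int i = 0; i < n; ++i) logv[i] = std::log(v[i]);
  suffix[n] = 0.0;
  for (int i = n - 1; i >= 0; --i) suffix[i] = suffix[i + 1] + logv[i];

  double fallback = NA_REAL;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && v[i] == v[i - 1]) continue;  // unique candidates only
    const int m = n - i;
    if (m < minTail) break;
    fallback = v[i];  // ends at the rightmost admissible candidate
    const double denom = suffix[i] - m * logv[i];
    if (denom <= 0.0) continue;  // tail all equal to xmin
    const double alpha = 1.0 + m / denom;
    double D = 0.0;
    for (int j = 0; j < m; ++j) {
      const double Ft = 1.0 - std::pow(v[i + j] / v[i], 1.0 - alpha);
      const double lo = std::fabs(Ft - static_cast<double>(j) / m);
      const double hi = std::fabs(Ft - static_cast<double>(j + 1) / m);
      if (lo > D) D = lo;
      if (hi > D) D = hi;
    }
    if (std::sqrt(static_cast<double>(m)) * D <= ksCritical &&
        alpha <= alphaMax)
      return v[i];
  }
  return fallback;
}
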