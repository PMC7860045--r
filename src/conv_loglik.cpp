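// Marginal log-density of fluorescence readings under the measurement
// equation Y = eps + kappa * X, with X on a truncated support {0..K} with
// log-pmf `logw` and eps skew-normal SN(a, xi, omega) in the standard
// Azzalini location/scale form.  The sum over x is windowed to the region
// where the background density is non-negligible (|z| <= zmax).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".sn_conv_logdens")]]
NumericVector sn_conv_logdens(NumericVector y, NumericVector logw,
                              double kappa, double a, double xi, double omega,
                              double zmax = 12.0) {
  const R_xlen_t n = y.size();
  const int K = static_cast<int>(logw.size()) - 1;
  NumericVector out(n);
  const double log2 = std::log(2.0);
  const double logomega = std::log(omega);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double yi = y[i];
    // x-window where |(yi - kappa x - xi)/omega| <= zmax
    int lo = 0, hi = K;
    if (kappa > 0.0) {
      lo = static_cast<int>(std::ceil((yi - xi - zmax * omega) / kappa));
      hi = static_cast<int>(std::floor((yi - xi + zmax * omega) / kappa));
      if (lo < 0) lo = 0;
      if (hi > K) hi = K;
    }
    if (lo > hi) { out[i] = R_NegInf; continue; }
    double m = R_NegInf;
    // fast path: inline normal log-density and erfc-based log-Phi
    // (stable log-sum-exp over the window)
    const int w = hi - lo + 1;
    std::vector<double> terms(w);
    const double log_sqrt2pi = 0.9189385332046727;
    for (int x = lo; x <= hi; ++x) {
      const double z = (yi - kappa * x - xi) / omega;
      const double phi = 0.5 * std::erfc(-a * z * M_SQRT1_2);
      const double lt = logw[x] + log2 - logomega -
        0.5 * z * z - log_sqrt2pi + std::log(phi);
      terms[x - lo] = lt;
      if (lt > m) m = lt;
    }
    if (!std::isfinite(m)) {
      // accurate fallback for deep-tail points where erfc underflowed
      m = R_NegInf;
      for (int x = lo; x <= hi; ++x) {
        const double z = (yi - kappa * x - xi) / omega;
        const double lt = logw[x] + log2 - logomega +
          R::dnorm(z, 0.0, 1.0, 1) + R::pnorm(a * z, 0.0, 1.0, 1, 1);
        terms[x - lo] = lt;
        if (lt > m) m = lt;
      }
      if (!std::isfinite(m)) { out[i] = R_NegInf; continue; }
    }
    double s = 0.0;
    for (int j = 0; j < w; ++j) s += std::exp(terms[j] - m);
    out[i] = m + std::log(s);
  }
  return out;
}
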