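#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Scalar constant-position (random-walk) Kalman recursion along a profile.
// State is initialised at the first measurement with covariance p0; each
// subsequent step predicts (covariance += q) and updates with gain
// K = P / (P + r).
// [[Rcpp::export(name = ".kalman_core")]]
NumericVector kalman_core(NumericVector z, double q, double r, double p0) {
  int n = z.size();
  NumericVector out(n);
  double x = z[0];
  double p = p0;
  out[0] = x;
  for (int k = 1; k < n; ++k) {
    p += q;
    double gain = p / (p + r);
    x += gain * (z[k] - x);
    p *= (1.0 - gain);
    out[k] = x;
  }
  return out;
}

// Iterates the covariance recursion only; returns the gain at each step.
// Used to expose steady-state behaviour without touching data.
// [[Rcpp::export(name = ".kalman_gain_seq")]]
NumericVector kalman_gain_seq(int n, double q, double r, double p0) {
  NumericVector gains(n);
  double p = p0;
  for (int k = 0; k < n; ++k) {
    p += q;
    double gain = p / (p + r);
    gains[k] = gain;
    p *= (1.0 - gain);
  }
  return gains;
}

// Sliding-window median with offsets [-left, +right] around each index;
// windows are truncated at the edges (no padding).
// [[Rcpp::export(name = ".median_core")]]
NumericVector median_core(NumericVector z, int left, int right) {
  int n = z.size();
  NumericVector out(n);
  std::vector<double> w;
  w.reserve(left + right + 1);
  for (int k = 0; k < n; ++k) {
    int lo = std::max(0, k - left);
    int hi = std::min(n - 1, k + right);
    w.assign(z.begin() + lo, z.begin() + hi + 1);
    int m = w.size();
    std::sort(w.begin(), w.end());
    out[k] = (m % 2 == 1) ? w[m / 2] : 0.5 * (w[m / 2 - 1] + w[m / 2]);
  }
  return out;
}
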