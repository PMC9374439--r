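// Compiled Wiener first-passage-time log-density, mirroring the R
// implementation (small/large-time series with adaptive truncation and
// signed log-sum-exp). Used in the MCMC hot path; equality with the R
// reference is asserted in tests.
#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454835606594728112;

// log f1(u, w) in normalized time via the small-time expansion
static double f1_small_log(double u, double w, double K) {
  int Ki = (int)std::ceil(K);
  double m = R_NegInf;
  // first pass: maximum log magnitude
  for (int k = -Ki; k <= Ki; ++k) {
    double s = w + 2.0 * k;
    if (s == 0.0) continue;
    double lm = std::log(std::fabs(s)) - s * s / (2.0 * u);
    if (lm > m) m = lm;
  }
  if (!R_finite(m)) return R_NegInf;
  double acc = 0.0;
  for (int k = -Ki; k <= Ki; ++k) {
    double s = w + 2.0 * k;
    if (s == 0.0) continue;
    double lm = std::log(std::fabs(s)) - s * s / (2.0 * u);
    acc += (s > 0 ? 1.0 : -1.0) * std::exp(lm - m);
  }
  if (acc <= 0.0) return R_NegInf;
  return m + std::log(acc) - 0.5 * LOG_2PI - 1.5 * std::log(u);
}

// log f1(u, w) via the large-time (eigenfunction) expansion
static double f1_large_log(double u, double w, double K) {
  int Ki = (int)std::ceil(K);
  if (Ki < 1) Ki = 1;
  double m = R_NegInf;
  for (int k = 1; k <= Ki; ++k) {
    double sk = std::sin(k * M_PI * w);
    if (sk == 0.0) continue;
    double lm = std::log((double)k) - k * k * M_PI * M_PI * u / 2.0 +
                std::log(std::fabs(sk));
    if (lm > m) m = lm;
  }
  if (!R_finite(m)) return R_NegInf;
  double acc = 0.0;
  for (int k = 1; k <= Ki; ++k) {
    double sk = std::sin(k * M_PI * w);
    if (sk == 0.0) continue;
    double lm = std::log((double)k) - k * k * M_PI * M_PI * u / 2.0 +
                std::log(std::fabs(sk));
    acc += (sk > 0 ? 1.0 : -1.0) * std::exp(lm - m);
  }
  if (acc <= 0.0) return R_NegInf;
  return m + std::log(acc) + std::log(M_PI);
}

// [[Rcpp::export(name = ".wfpt_logd_cpp")]]
NumericVector wfpt_logd_cpp(IntegerVector choice, NumericVector rt, double v,
                            double a, double w, double tau, double err_tol) {
  int n = rt.size();
  NumericVector out(n, R_NegInf);
  double a2 = a * a;
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - tau;
    if (!R_finite(t) || t <= 0.0) continue;
    double vv = v, ww = w;
    if (choice[i] == 1) { vv = -v; ww = 1.0 - w; }
    double u = t / a2;
    // terms needed by each expansion at this tolerance
    double ks = 2.0;
    if (2.0 * std::sqrt(2.0 * M_PI * u) * err_tol < 1.0)
      ks = 2.0 + std::sqrt(-2.0 * u *
                           std::log(2.0 * err_tol * std::sqrt(2.0 * M_PI * u)));
    double ks_min = std::sqrt(u) + 1.0;
    if (ks < ks_min) ks = ks_min;
    double kl = 1.0 / (M_PI * std::sqrt(u));
    if (M_PI * u * err_tol < 1.0) {
      double kl2 = std::sqrt(-2.0 * std::log(M_PI * u * err_tol) /
                             (M_PI * M_PI * u));
      if (kl2 > kl) kl = kl2;
    }
    double logf1 = (ks < kl) ? f1_small_log(u, ww, ks) : f1_large_log(u, ww, kl);
    out[i] = -2.0 * std::log(a) - vv * a * ww - vv * vv * t / 2.0 + logf1;
  }
  return out;
}
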