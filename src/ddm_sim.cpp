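// Euler-Maruyama simulation of the drift-diffusion model (constant and
// linearly collapsing bounds), with per-trial counter-based RNG streams so
// that results do not depend on how trials are batched.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64: small, fast, statistically solid for this use.
static inline uint64_t sm64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double sm64_unif(uint64_t &state) {
  // (0, 1): top 53 bits, offset by half an ulp to exclude 0
  return ((sm64_next(state) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct TrialRng {
  uint64_t state;
  bool have_spare;
  double spare;
  TrialRng(uint64_t seed, uint64_t trial, uint64_t attempt) {
    // mix seed, trial index and resimulation attempt into one stream key
    uint64_t s = seed;
    uint64_t k = sm64_next(s) ^ (trial * 0xD2B74407B1CE6E93ULL) ^
                 (attempt * 0xCA5A826395121157ULL);
    state = k;
    (void)sm64_next(state); // warm up
    have_spare = false;
    spare = 0.0;
  }
  double unif() { return sm64_unif(state); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// Simulate a single trial; returns first-passage (decision) time in `t` and
// choice in `c` (1 = upper bound, 0 = lower bound). `forced` is set when the
// collapsing bounds pinch before absorption. Returns false if not absorbed
// by max_t.
static bool sim_one(TrialRng &rng, double v, double a, double w, double gamma,
                    double dt, double max_t, double &t, int &c, bool &forced) {
  double x = w * a;
  double sdt = std::sqrt(dt);
  double tt = 0.0;
  forced = false;
  // pinch time for collapsing bounds: a + gamma*t = -gamma*t  =>  t = -a/(2 gamma)
  double pinch = (gamma < 0.0) ? (a / (-2.0 * gamma)) : R_PosInf;
  double bridge_cut = 9.0 * dt; // exp(-2*9) ~ 1.5e-8: negligible beyond this
  while (tt < max_t) {
    double b_up, b_lo;
    if (gamma < 0.0) {
      if (tt >= pinch) { // bounds met: force a decision at the pinch
        forced = true;
        c = (x >= a / 2.0) ? 1 : 0;
        t = tt;
        return true;
      }
      b_up = a + gamma * tt;
      b_lo = -gamma * tt;
    } else {
      b_up = a;
      b_lo = 0.0;
    }
    double x_new = x + v * dt + sdt * rng.norm();
    double t_new = tt + dt;
    if (x_new >= b_up) { c = 1; t = t_new; return true; }
    if (x_new <= b_lo) { c = 0; t = t_new; return true; }
    // Brownian-bridge correction: probability of an unobserved within-step
    // crossing; removes the O(sqrt(dt)) discretization bias at the bounds.
    double du = (b_up - x) * (b_up - x_new);
    if (du < bridge_cut) {
      if (rng.unif() < std::exp(-2.0 * du / dt)) { c = 1; t = t_new; return true; }
    }
    double dl = (x - b_lo) * (x_new - b_lo);
    if (dl < bridge_cut) {
      if (rng.unif() < std::exp(-2.0 * dl / dt)) { c = 0; t = t_new; return true; }
    }
    x = x_new;
    tt = t_new;
  }
  return false;
}

// [[Rcpp::export(name = ".ddm_sim_cpp")]]
List ddm_sim_cpp(int n_trials, NumericVector v, NumericVector a,
                 NumericVector w, NumericVector tau, NumericVector gamma,
                 double dt, double max_t, double seed, int max_retries) {
  int np = v.size();
  bool per_trial_params = (np > 1);
  if (per_trial_params && np != n_trials)
    stop("parameter vectors must have length 1 or n_trials");
  IntegerVector choice(n_trials);
  NumericVector rt(n_trials);
  LogicalVector forced_flag(n_trials);
  uint64_t useed = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n_trials; ++i) {
    int j = per_trial_params ? i : 0;
    double t;
    int c;
    bool forced;
    bool ok = false;
    for (int attempt = 0; attempt <= max_retries; ++attempt) {
      TrialRng rng(useed, (uint64_t)i, (uint64_t)attempt);
      ok = sim_one(rng, v[j], a[j], w[j], gamma[j], dt, max_t, t, c, forced);
      if (ok) break;
    }
    if (!ok)
      stop("trial %d not absorbed within max_t = %.2f s after %d attempts; "
           "increase max_t", i + 1, max_t, max_retries + 1);
    choice[i] = c;
    rt[i] = tau[j] + t;
    forced_flag[i] = forced;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["forced"] = forced_flag);
}
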