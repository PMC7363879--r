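// Core diffusion simulator and simulation-based KDE likelihood.
//
// The evidence accumulator is integrated by Euler-Maruyama on a fixed grid:
//   x_{i+1} = x_i + mu(t_i) * dt + noise_sd * sqrt(dt) * N(0,1)
// with symmetric collapsing bounds +/- b * exp(-d * t) checked after every
// step.  The drift series mu(t) is deterministic given the parameters and the
// trial's gaze timeline, so it is precomputed once per (trial, parameter)
// pair and shared by all simulations of that trial.
//
// Normal variates come from a xoshiro256++ generator with a 128-layer
// ziggurat; R never sees this generator directly — every entry point takes a
// seed derived from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstdlib>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// ------------------------------------------------------------------ RNG ----

namespace addmrng {

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline uint32_t next32() { return static_cast<uint32_t>(next() >> 32); }
  inline double unif() {  // uniform on (0, 1), 53-bit
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Marsaglia & Tsang ziggurat for the standard normal (128 layers).
static uint32_t kn[128];
static double wn[128], fn[128];
static bool zig_ready = false;

static void zigset() {
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  kn[0] = static_cast<uint32_t>((dn / q) * m1);
  kn[1] = 0;
  wn[0] = q / m1;
  wn[127] = dn / m1;
  fn[0] = 1.0;
  fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; --i) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
    tn = dn;
    fn[i] = std::exp(-0.5 * dn * dn);
    wn[i] = dn / m1;
  }
  zig_ready = true;
}

static double nfix(Xoshiro256& rng, int32_t hz, uint32_t iz) {
  const double r = 3.442619855899;
  double x, y;
  for (;;) {
    x = hz * wn[iz];
    if (iz == 0) {  // base strip: exponential tail
      do {
        x = -std::log(rng.unif()) / r;
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -(r + x);
    }
    if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
    hz = static_cast<int32_t>(rng.next32());
    iz = static_cast<uint32_t>(hz) & 127u;
    uint32_t ahz = (hz < 0) ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                            : static_cast<uint32_t>(hz);
    if (ahz < kn[iz]) return hz * wn[iz];
  }
}

static inline double rnorm_zig(Xoshiro256& rng) {
  int32_t hz = static_cast<int32_t>(rng.next32());
  uint32_t iz = static_cast<uint32_t>(hz) & 127u;
  uint32_t ahz = (hz < 0) ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
                          : static_cast<uint32_t>(hz);
  return (ahz < kn[iz]) ? hz * wn[iz] : nfix(rng, hz, iz);
}

}  // namespace addmrng

// [[Rcpp::export]]
NumericVector cpp_rnorm(int n, double seed) {
  if (!addmrng::zig_ready) addmrng::zigset();
  addmrng::Xoshiro256 rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = addmrng::rnorm_zig(rng);
  return out;
}

// ---------------------------------------------------------------- model ----

// parameter vector layout (length 10):
// 0 w_self, 1 w_other, 2 w_fair, 3 b, 4 d, 5 stbias, 6 genbias, 7 theta,
// 8 percept (gaze model) / ndt (static model), 9 motor (gaze model only)
enum { P_WSELF, P_WOTHER, P_WFAIR, P_B, P_D, P_STB, P_GENB, P_THETA,
       P_PERCEPT, P_MOTOR };

struct DriftPlan {
  int n_steps;
  std::vector<double> mu;     // drift (per s) at each step's left endpoint
  std::vector<double> bound;  // bound at t_j = j * dt, j = 0..n_steps
  double z;
  double entry_self_s, entry_other_s;  // first-fixation onsets (Inf if none)
};

// Build the deterministic drift/bound plan for one trial.
static void build_plan(DriftPlan& plan, const double* par, bool gaze_model,
                       double self, double other, double deadline,
                       const int* seg_aoi, const double* seg_on,
                       const double* seg_off, int n_seg, double dt) {
  const double inf = std::numeric_limits<double>::infinity();
  const double theta = gaze_model ? par[P_THETA] : 0.0;
  const double w_self = par[P_WSELF], w_other = par[P_WOTHER];
  const double w_fair = par[P_WFAIR];
  const double fair = std::fabs(self - other);
  const double pms = gaze_model ? par[P_PERCEPT] * 1000.0 : 0.0;

  int n_steps = static_cast<int>(std::ceil(deadline / dt - 1e-9));
  plan.n_steps = n_steps;
  plan.mu.assign(n_steps, 0.0);
  plan.bound.assign(n_steps + 1, 0.0);

  // collapsing bound via recurrence
  const double decay = std::exp(-par[P_D] * dt);
  double bnd = par[P_B];
  for (int j = 0; j <= n_steps; ++j) {
    plan.bound[j] = bnd;
    bnd *= decay;
  }

  // start point (Eq. on the accept/reject bias)
  double z = par[P_STB];
  if (self < other) z += par[P_GENB];
  else if (self > other) z -= par[P_GENB];
  plan.z = z;

  if (!gaze_model) {
    const double mu = w_self * self + w_other * other + w_fair * fair;
    std::fill(plan.mu.begin(), plan.mu.end(), mu);
    plan.entry_self_s = inf;
    plan.entry_other_s = inf;
    return;
  }

  // first entries into each AOI (ms)
  double es = inf, eo = inf;
  for (int k = 0; k < n_seg; ++k) {
    if (seg_aoi[k] == 1 && !std::isfinite(es)) es = seg_on[k];
    if (seg_aoi[k] == 2 && !std::isfinite(eo)) eo = seg_on[k];
    if (std::isfinite(es) && std::isfinite(eo)) break;
  }
  plan.entry_self_s = es / 1000.0;
  plan.entry_other_s = eo / 1000.0;

  // mu(t) is piecewise constant; fill it between its breakpoints (segment
  // edges, first entries and percept-window closings) instead of per step
  const double dt_ms = dt * 1000.0;
  const double dl_ms = deadline * 1000.0;
  std::vector<double> bp;
  bp.reserve(2 * n_seg + 6);
  bp.push_back(0.0);
  for (int k = 0; k < n_seg; ++k) {
    if (seg_on[k] > 0.0 && seg_on[k] < dl_ms) bp.push_back(seg_on[k]);
    if (seg_off[k] > 0.0 && seg_off[k] < dl_ms) bp.push_back(seg_off[k]);
  }
  for (double e : {es, es + pms, eo, eo + pms}) {
    if (std::isfinite(e) && e > 0.0 && e < dl_ms) bp.push_back(e);
  }
  bp.push_back(dl_ms);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  int seg = 0;
  for (size_t q = 0; q + 1 < bp.size(); ++q) {
    const double t = bp[q];  // constant on [bp[q], bp[q+1])
    while (seg < n_seg - 1 && t >= seg_off[seg]) ++seg;
    int aoi = 0;
    if (seg < n_seg && t >= seg_on[seg] && t < seg_off[seg]) aoi = seg_aoi[seg];

    const bool in_ws = (t >= es && t < es + pms);
    const bool in_wo = (t >= eo && t < eo + pms);
    // an attribute counts as seen once its percept window has completed
    const bool seen_s = (es + pms <= t);
    const bool seen_o = (eo + pms <= t);

    double mu;
    if (in_ws || in_wo) {  // perceptual intake: only prior information drives
      if (seen_s)      mu = (1.0 - theta) * w_self * self;
      else if (seen_o) mu = (1.0 - theta) * w_other * other;
      else             mu = 0.0;
    } else {
      const double a_s = (aoi == 1) ? 1.0 : (1.0 - theta);
      const double a_o = (aoi == 2) ? 1.0 : (1.0 - theta);
      mu = 0.0;
      if (seen_s) mu += a_s * w_self * self;
      if (seen_o) mu += a_o * w_other * other;
      if (seen_s && seen_o) mu += w_fair * fair;
    }
    // steps whose left endpoint i * dt_ms lies in [bp[q], bp[q+1])
    int i0 = static_cast<int>(std::ceil(t / dt_ms - 1e-9));
    int i1 = static_cast<int>(std::ceil(bp[q + 1] / dt_ms - 1e-9));
    if (i1 > n_steps) i1 = n_steps;
    for (int i = i0; i < i1; ++i) plan.mu[i] = mu;
  }
}

struct SimResult {
  int choice;       // 0 accept, 1 reject, 2 missed
  double rt;        // NA-equivalent (-1) when missed
  double dec_time;
  int n_uniq;
};

static inline void simulate_one(const DriftPlan& plan, const double* par,
                                bool gaze_model, double deadline, double dt,
                                double noise_sd, addmrng::Xoshiro256& rng,
                                SimResult& out) {
  const double sq = noise_sd * std::sqrt(dt);
  double x = plan.z;
  int sign = 0;
  double td = -1.0;

  if (std::fabs(x) >= plan.bound[0]) {  // degenerate: start outside bounds
    td = 0.0;
    if (x > 0) sign = +1;
    else if (x < 0) sign = -1;
    else sign = (rng.unif() < 0.5) ? +1 : -1;
  } else {
    const int n = plan.n_steps;
    const double* mu = plan.mu.data();
    const double* bd = plan.bound.data();
    // beyond COARSE_AFTER_S the grid coarsens by COARSE_FACTOR: only slow
    // tails (long low-pressure trials) are affected, where the crossing-time
    // granularity is far below the KDE bandwidth
    const double COARSE_AFTER_S = 1.6;
    const int COARSE_FACTOR = 8;
    const int n_fine = std::min(
        n, static_cast<int>(std::ceil(COARSE_AFTER_S / dt)));
    int i = 0;
    for (; i < n_fine; ++i) {
      x += mu[i] * dt + sq * addmrng::rnorm_zig(rng);
      const double b1 = bd[i + 1];
      if (x >= b1) { sign = +1; td = (i + 1) * dt; break; }
      if (x <= -b1) { sign = -1; td = (i + 1) * dt; break; }
    }
    if (sign == 0 && i >= n_fine) {
      while (i < n) {
        const int stride = std::min(COARSE_FACTOR, n - i);
        x += mu[i] * (dt * stride) +
             sq * std::sqrt(static_cast<double>(stride)) *
                 addmrng::rnorm_zig(rng);
        i += stride;
        const double b1 = bd[i];
        if (x >= b1) { sign = +1; td = i * dt; break; }
        if (x <= -b1) { sign = -1; td = i * dt; break; }
      }
    }
  }

  if (sign == 0) {  // never crossed before the deadline
    out.choice = 2; out.rt = -1.0; out.dec_time = -1.0; out.n_uniq = 0;
    return;
  }
  int n_uniq = 0;
  double rt;
  if (gaze_model) {
    if (plan.entry_self_s < td) ++n_uniq;
    if (plan.entry_other_s < td) ++n_uniq;
    rt = td + par[P_MOTOR] + n_uniq * par[P_PERCEPT];
  } else {
    rt = td + par[P_PERCEPT];  // slot 8 holds ndt for the static model
  }
  if (rt > deadline + 1e-12) {
    out.choice = 2; out.rt = -1.0; out.dec_time = td; out.n_uniq = n_uniq;
  } else {
    out.choice = (sign > 0) ? 0 : 1;
    out.rt = rt; out.dec_time = td; out.n_uniq = n_uniq;
  }
}

// Simulate one trial n_sims times; returns choices/rts/decision times.
// [[Rcpp::export]]
List cpp_sim_trial(NumericVector par, bool gaze_model, double self,
                   double other, double deadline, IntegerVector seg_aoi,
                   NumericVector seg_on, NumericVector seg_off, int n_sims,
                   double dt, double noise_sd, double seed) {
  if (!addmrng::zig_ready) addmrng::zigset();
  addmrng::Xoshiro256 rng(static_cast<uint64_t>(seed));
  DriftPlan plan;
  build_plan(plan, par.begin(), gaze_model, self, other, deadline,
             seg_aoi.begin(), seg_on.begin(), seg_off.begin(), seg_aoi.size(),
             dt);
  IntegerVector choice(n_sims), nuniq(n_sims);
  NumericVector rt(n_sims), dtime(n_sims);
  SimResult res;
  for (int s = 0; s < n_sims; ++s) {
    simulate_one(plan, par.begin(), gaze_model, deadline, dt, noise_sd, rng,
                 res);
    choice[s] = res.choice;
    rt[s] = (res.choice == 2) ? NA_REAL : res.rt;
    dtime[s] = (res.dec_time < 0) ? NA_REAL : res.dec_time;
    nuniq[s] = res.n_uniq;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt,
                      _["decision_time"] = dtime, _["n_unique"] = nuniq);
}

// Drift series (per s) for one trial — exposed for parity tests against the
// R-level momentary drift function.
// [[Rcpp::export]]
NumericVector cpp_drift_series(NumericVector par, bool gaze_model, double self,
                               double other, double deadline,
                               IntegerVector seg_aoi, NumericVector seg_on,
                               NumericVector seg_off, double dt) {
  DriftPlan plan;
  build_plan(plan, par.begin(), gaze_model, self, other, deadline,
             seg_aoi.begin(), seg_on.begin(), seg_off.begin(), seg_aoi.size(),
             dt);
  return NumericVector(plan.mu.begin(), plan.mu.end());
}

// ----------------------------------------------------------- likelihood ----

// R type-7 quantile on a sorted vector
static double quantile7(const std::vector<double>& x, double p) {
  const int n = static_cast<int>(x.size());
  if (n == 1) return x[0];
  const double h = (n - 1) * p;
  const int lo = static_cast<int>(std::floor(h));
  const int hi = std::min(lo + 1, n - 1);
  return x[lo] + (h - lo) * (x[hi] - x[lo]);
}

// Halved Silverman rule-of-thumb bandwidth; fallback when degenerate.
static double silverman_halved(std::vector<double>& x, double fallback) {
  const int n = static_cast<int>(x.size());
  if (n < 2) return fallback;
  std::sort(x.begin(), x.end());
  bool distinct = false;
  for (int i = 1; i < n; ++i)
    if (x[i] != x[0]) { distinct = true; break; }
  if (!distinct) return fallback;
  double mean = 0.0;
  for (double v : x) mean += v;
  mean /= n;
  double ss = 0.0;
  for (double v : x) ss += (v - mean) * (v - mean);
  const double sd = std::sqrt(ss / (n - 1));
  const double iqr = quantile7(x, 0.75) - quantile7(x, 0.25);
  const double a = std::min(sd, iqr / 1.34);
  double h = 0.5 * 0.9 * a * std::pow(static_cast<double>(n), -0.2);
  if (!std::isfinite(h) || h <= 0.0) h = fallback;
  return h;
}

static double kde_class_loglik(std::vector<double>& rts, int n_total,
                               double obs_rt, double eps, double fallback_bw) {
  const int m = static_cast<int>(rts.size());
  if (m == 0) return std::log(eps);
  const double h = silverman_halved(rts, fallback_bw);
  const double c = 1.0 / (h * 2.5066282746310002);  // 1 / (h * sqrt(2*pi))
  double dens = 0.0;
  for (double v : rts) {
    const double u = (obs_rt - v) / h;
    dens += std::exp(-0.5 * u * u);
  }
  dens = c * dens / m;
  double lik = (static_cast<double>(m) / n_total) * dens;
  if (!(lik > eps)) lik = eps;
  return std::log(lik);
}

// Likelihood of one observed trial from pre-simulated class samples.
// obs_choice: 0 accept, 1 reject, 2 missed.
// [[Rcpp::export]]
double cpp_kde_loglik(NumericVector accept_rts, NumericVector reject_rts,
                      int n_missed, int n_total, int obs_choice, double obs_rt,
                      double eps, double fallback_bw) {
  if (obs_choice == 2) {
    double lik = static_cast<double>(n_missed) / n_total;
    if (!(lik > eps)) lik = eps;
    return std::log(lik);
  }
  std::vector<double> rts;
  if (obs_choice == 0) rts.assign(accept_rts.begin(), accept_rts.end());
  else rts.assign(reject_rts.begin(), reject_rts.end());
  return kde_class_loglik(rts, n_total, obs_rt, eps, fallback_bw);
}

// Full-subject log-likelihood: simulate every trial n_sims times under the
// condition-specific parameters and score the observed (choice, RT) pairs by
// class-weighted Gaussian KDE (missed trials by their simulated frequency).
//
// cond: 1 = high time pressure, -1 = low (selects par_high / par_low)
// obs_choice: 0 accept, 1 reject, 2 missed; obs_rt in s (ignored if missed)
// Gaze segments are passed flattened with 0-based trial offsets trial_ptr
// (length n_trials + 1).
// [[Rcpp::export]]
double cpp_dataset_loglik(NumericVector par_high, NumericVector par_low,
                          bool gaze_model, NumericVector self,
                          NumericVector other, NumericVector deadline,
                          IntegerVector cond, IntegerVector obs_choice,
                          NumericVector obs_rt, IntegerVector seg_aoi,
                          NumericVector seg_on, NumericVector seg_off,
                          IntegerVector trial_ptr, int n_sims, double dt,
                          double noise_sd, double eps, double fallback_bw,
                          double seed) {
  if (!addmrng::zig_ready) addmrng::zigset();
  addmrng::Xoshiro256 rng(static_cast<uint64_t>(seed));
  const int n_trials = self.size();
  DriftPlan plan;
  std::vector<double> acc, rej;
  acc.reserve(n_sims);
  rej.reserve(n_sims);
  SimResult res;
  double ll = 0.0;
  for (int tr = 0; tr < n_trials; ++tr) {
    const double* par =
        (cond[tr] > 0) ? par_high.begin() : par_low.begin();
    const int k0 = trial_ptr[tr], k1 = trial_ptr[tr + 1];
    build_plan(plan, par, gaze_model, self[tr], other[tr], deadline[tr],
               seg_aoi.begin() + k0, seg_on.begin() + k0, seg_off.begin() + k0,
               k1 - k0, dt);
    acc.clear();
    rej.clear();
    int miss = 0;
    for (int s = 0; s < n_sims; ++s) {
      simulate_one(plan, par, gaze_model, deadline[tr], dt, noise_sd, rng,
                   res);
      if (res.choice == 0) acc.push_back(res.rt);
      else if (res.choice == 1) rej.push_back(res.rt);
      else ++miss;
    }
    if (obs_choice[tr] == 2) {
      double lik = static_cast<double>(miss) / n_sims;
      if (!(lik > eps)) lik = eps;
      ll += std::log(lik);
    } else if (obs_choice[tr] == 0) {
      ll += kde_class_loglik(acc, n_sims, obs_rt[tr], eps, fallback_bw);
    } else {
      ll += kde_class_loglik(rej, n_sims, obs_rt[tr], eps, fallback_bw);
    }
  }
  return ll;
}

// Per-trial predictive summaries at fixed parameters: P(accept), P(reject),
// P(missed), mean RT and mean log RT among responded simulations, and the
// fraction of simulations that would count as a generous response.
// generous_dir: +1 if ACCEPT is the generous response for this trial, -1 if
// REJECT is, 0 if the proposal has no self/other trade-off.
// [[Rcpp::export]]
NumericMatrix cpp_predict_trials(NumericVector par_high, NumericVector par_low,
                                 bool gaze_model, NumericVector self,
                                 NumericVector other, NumericVector deadline,
                                 IntegerVector cond, IntegerVector generous_dir,
                                 IntegerVector seg_aoi, NumericVector seg_on,
                                 NumericVector seg_off, IntegerVector trial_ptr,
                                 int n_sims, double dt, double noise_sd,
                                 double seed) {
  if (!addmrng::zig_ready) addmrng::zigset();
  addmrng::Xoshiro256 rng(static_cast<uint64_t>(seed));
  const int n_trials = self.size();
  NumericMatrix out(n_trials, 6);
  colnames(out) = CharacterVector::create("p_accept", "p_reject", "p_missed",
                                          "mean_rt", "mean_logrt",
                                          "p_generous");
  DriftPlan plan;
  SimResult res;
  for (int tr = 0; tr < n_trials; ++tr) {
    const double* par =
        (cond[tr] > 0) ? par_high.begin() : par_low.begin();
    const int k0 = trial_ptr[tr], k1 = trial_ptr[tr + 1];
    build_plan(plan, par, gaze_model, self[tr], other[tr], deadline[tr],
               seg_aoi.begin() + k0, seg_on.begin() + k0, seg_off.begin() + k0,
               k1 - k0, dt);
    int n_acc = 0, n_rej = 0, n_miss = 0;
    double sum_rt = 0.0, sum_lrt = 0.0;
    for (int s = 0; s < n_sims; ++s) {
      simulate_one(plan, par, gaze_model, deadline[tr], dt, noise_sd, rng,
                   res);
      if (res.choice == 2) { ++n_miss; continue; }
      if (res.choice == 0) ++n_acc; else ++n_rej;
      sum_rt += res.rt;
      sum_lrt += std::log(res.rt);
    }
    const int n_resp = n_acc + n_rej;
    out(tr, 0) = static_cast<double>(n_acc) / n_sims;
    out(tr, 1) = static_cast<double>(n_rej) / n_sims;
    out(tr, 2) = static_cast<double>(n_miss) / n_sims;
    out(tr, 3) = (n_resp > 0) ? sum_rt / n_resp : NA_REAL;
    out(tr, 4) = (n_resp > 0) ? sum_lrt / n_resp : NA_REAL;
    if (generous_dir[tr] == 0 || n_resp == 0) {
      out(tr, 5) = NA_REAL;
    } else {
      const int n_gen = (generous_dir[tr] > 0) ? n_acc : n_rej;
      out(tr, 5) = static_cast<double>(n_gen) / n_resp;
    }
  }
  return out;
}
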