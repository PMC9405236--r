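#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shared forward-Euler core for the continuous ADEX neuron and its N-LUT
// variant.  The trace stores V clamped at `apex` (top of the hardware
// operating range) so that spike apices are bounded; the state itself is
// reset on the step after the V > 0 crossing.

static inline double adx_exact(double v, double gL, double EL, double VT,
                               double DeltaT, double expClamp) {
  double arg = (v - VT) / DeltaT;
  if (arg > expClamp) arg = expClamp;
  return -gL * (v - EL) + gL * DeltaT * std::exp(arg);
}

static inline double lut_read(double v, const double* vals, int n,
                              double vmin, double dv) {
  double x = (v - vmin) / dv;
  long k = std::lround(x);
  if (k < 0) k = 0;
  if (k >= n) k = n - 1;
  return vals[k];
}

// [[Rcpp::export(name = ".sim_adex_cpp")]]
List sim_adex_cpp(NumericVector par, double dt, int n_steps,
                  double v0, double w0, double exp_clamp, double apex,
                  bool use_lut, NumericVector lut_vals,
                  double lut_vmin, double lut_dv) {
  double C = par[0], gL = par[1], EL = par[2], VT = par[3], DeltaT = par[4],
         a = par[5], tau_w = par[6], b = par[7], Vr = par[8], I = par[9];
  NumericVector V(n_steps + 1), W(n_steps + 1);
  std::vector<int> spikes;
  const double* lv = lut_vals.begin();
  int nl = lut_vals.size();
  double v = v0, w = w0;
  V[0] = std::min(v, apex);
  W[0] = w;
  for (int i = 1; i <= n_steps; ++i) {
    if (v > 0.0) {  // reset belongs to the step after the recorded apex
      v = Vr;
      w = w + b;
    }
    double fx = use_lut ? lut_read(v, lv, nl, lut_vmin, lut_dv)
                        : adx_exact(v, gL, EL, VT, DeltaT, exp_clamp);
    double dv = (fx + I - w) / C;
    double dw = (a * (v - EL) - w) / tau_w;
    v += dt * dv;
    w += dt * dw;
    if (!std::isfinite(v) || !std::isfinite(w))
      stop("state diverged (non-finite V or W) at step %d (t = %g ms)",
           i, i * dt);
    V[i] = std::min(v, apex);
    W[i] = w;
    if (v > 0.0) spikes.push_back(i);  // sample index of the recorded apex
  }
  return List::create(_["V"] = V, _["W"] = W,
                      _["spike_idx"] = wrap(spikes));
}

// ---------------------------------------------------------------------------
// Fixed-point multiplierless emulator.
//
// All state and constants are two's-complement integers with `frac_bits`
// fraction bits, saturated to `word_bits`.  Constant scalings are applied as
// canonical-signed-digit shift/add chains; the only other operations are
// additions, subtractions and LUT reads, tallied in an operation trace.

struct FxCtx {
  int64_t lo, hi;
  long n_sat = 0;
  long n_shift = 0, n_add = 0, n_sub = 0, n_lut = 0;
  int64_t sat(int64_t x) {
    if (x > hi) { ++n_sat; return hi; }
    if (x < lo) { ++n_sat; return lo; }
    return x;
  }
};

static inline int64_t ashift(int64_t v, int e) {
  // arithmetic shift by a signed exponent: e >= 0 left, e < 0 right
  if (e >= 0) return v << e;
  return v >> (-e);  // gcc/clang: arithmetic shift for signed operands
}

static inline int64_t csd_scale(int64_t v, const IntegerVector& expo,
                                const IntegerVector& sign, FxCtx& cx) {
  int64_t acc = 0;
  for (int t = 0; t < expo.size(); ++t) {
    int64_t term = cx.sat(ashift(v, expo[t]));
    ++cx.n_shift;
    if (t == 0) {
      acc = sign[t] > 0 ? term : cx.sat(-term);
    } else if (sign[t] > 0) {
      acc = cx.sat(acc + term);
      ++cx.n_add;
    } else {
      acc = cx.sat(acc - term);
      ++cx.n_sub;
    }
  }
  return acc;
}

// [[Rcpp::export(name = ".sim_fixed_cpp")]]
List sim_fixed_cpp(double I_fx, double EL_fx, double Vr_fx, double b_fx,
                   IntegerVector dtC_e, IntegerVector dtC_s,
                   IntegerVector dtTau_e, IntegerVector dtTau_s,
                   IntegerVector a_e, IntegerVector a_s,
                   NumericVector lut_fx, double lut_vmin, double lut_dv,
                   int word_bits, int frac_bits,
                   double v0_fx, double w0_fx, int n_steps, double apex_fx) {
  FxCtx cx;
  cx.hi = (int64_t(1) << (word_bits - 1)) - 1;
  cx.lo = -(int64_t(1) << (word_bits - 1));
  int64_t I = (int64_t)I_fx, EL = (int64_t)EL_fx, Vr = (int64_t)Vr_fx,
          b = (int64_t)b_fx, apx = (int64_t)apex_fx;
  std::vector<int64_t> lut(lut_fx.size());
  for (int i = 0; i < lut_fx.size(); ++i) lut[i] = (int64_t)lut_fx[i];
  double scale = std::ldexp(1.0, -frac_bits);
  int nl = lut.size();

  NumericVector Vraw(n_steps + 1), Wraw(n_steps + 1);
  std::vector<int> spikes;
  int64_t v = cx.sat((int64_t)v0_fx), w = cx.sat((int64_t)w0_fx);
  Vraw[0] = (double)std::min(v, apx);
  Wraw[0] = (double)w;
  for (int i = 1; i <= n_steps; ++i) {
    if (v > 0) {
      v = Vr;
      w = cx.sat(w + b);
      ++cx.n_add;
    }
    // ADX unit: SRAM read addressed by the quantised membrane voltage
    double vmv = (double)v * scale;
    long k = std::lround((vmv - lut_vmin) / lut_dv);
    if (k < 0) k = 0;
    if (k >= nl) k = nl - 1;
    int64_t fx = lut[k];
    ++cx.n_lut;
    // pipelining unit, V path: V' = V + (dt/C)*(ADX + I - W)
    int64_t t1 = cx.sat(fx + I);  ++cx.n_add;
    int64_t t2 = cx.sat(t1 - w);  ++cx.n_sub;
    int64_t dv = csd_scale(t2, dtC_e, dtC_s, cx);
    int64_t vn = cx.sat(v + dv);  ++cx.n_add;
    // W path: W' = W + (dt/tau_w)*(a*(V - EL) - W)
    int64_t u1 = cx.sat(v - EL);  ++cx.n_sub;
    int64_t u2 = csd_scale(u1, a_e, a_s, cx);
    int64_t u3 = cx.sat(u2 - w);  ++cx.n_sub;
    int64_t dw = csd_scale(u3, dtTau_e, dtTau_s, cx);
    w = cx.sat(w + dw);           ++cx.n_add;
    v = vn;
    Vraw[i] = (double)std::min(v, apx);
    Wraw[i] = (double)w;
    if (v > 0) spikes.push_back(i);
  }
  return List::create(
      _["V_raw"] = Vraw, _["W_raw"] = Wraw, _["spike_idx"] = wrap(spikes),
      _["ops"] = List::create(
          _["shift"] = (double)cx.n_shift, _["add"] = (double)cx.n_add,
          _["sub"] = (double)cx.n_sub, _["mul"] = 0.0, _["div"] = 0.0,
          _["exp"] = 0.0, _["lut_read"] = (double)cx.n_lut),
      _["n_saturations"] = (double)cx.n_sat);
}

// ---------------------------------------------------------------------------
// Population of randomly connected ADEX neurons (original or N-LUT kinetics).
// Delta-pulse synapses: weights of neurons that spiked on the previous step
// are summed into the postsynaptic stimulus current for one step.  Noise is
// drawn from R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export(name = ".sim_population_cpp")]]
List sim_population_cpp(NumericVector par, NumericVector I_i,
                        NumericVector v0, NumericVector w0,
                        IntegerVector adj_ptr, IntegerVector adj_post,
                        NumericVector adj_w,
                        double dt, int n_steps, double noise_sd,
                        double exp_clamp, bool use_lut,
                        NumericVector lut_vals, double lut_vmin,
                        double lut_dv) {
  double C = par[0], gL = par[1], EL = par[2], VT = par[3], DeltaT = par[4],
         a = par[5], tau_w = par[6], b = par[7], Vr = par[8];
  int N = I_i.size();
  std::vector<double> v(v0.begin(), v0.end()), w(w0.begin(), w0.end());
  std::vector<double> syn(N, 0.0), syn_next(N, 0.0);
  std::vector<char> fired(N, 0);
  std::vector<int> spk_id;
  std::vector<double> spk_t;
  const double* lv = lut_vals.begin();
  int nl = lut_vals.size();
  long n_clamped = 0;
  RNGScope rng;
  for (int i = 1; i <= n_steps; ++i) {
    std::fill(syn_next.begin(), syn_next.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      if (fired[j]) {
        for (int e = adj_ptr[j]; e < adj_ptr[j + 1]; ++e)
          syn_next[adj_post[e]] += adj_w[e];
      }
    }
    for (int j = 0; j < N; ++j) {
      double vj = v[j], wj = w[j];
      if (fired[j]) { vj = Vr; wj += b; fired[j] = 0; }
      double fx = use_lut ? lut_read(vj, lv, nl, lut_vmin, lut_dv)
                          : adx_exact(vj, gL, EL, VT, DeltaT, exp_clamp);
      double drive = I_i[j] + syn[j];
      if (noise_sd > 0.0) drive += noise_sd * norm_rand();
      double vn = vj + dt * (fx + drive - wj) / C;
      wj += dt * (a * (vj - EL) - wj) / tau_w;
      vj = vn;
      if (!std::isfinite(vj) || !std::isfinite(wj) || vj < -1000.0) {
        vj = Vr; wj = 0.0; ++n_clamped;
      }
      if (vj > 0.0) {
        fired[j] = 1;
        spk_id.push_back(j + 1);
        spk_t.push_back(i * dt);
      }
      v[j] = vj;
      w[j] = wj;
    }
    std::swap(syn, syn_next);
  }
  return List::create(_["neuron"] = wrap(spk_id), _["t"] = wrap(spk_t),
                      _["n_clamped"] = (double)n_clamped);
}
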