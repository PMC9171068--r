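// Adaptive exponential integrate-and-fire neuron with a first-order
// H-type (sag) conductance, integrated by exponential Euler on the linear
// parts with the spike-initiation exponential treated explicitly.
//
// Units: mV, ms, pA, nS, pF (so pF*mV/ms = pA and nS*mV = pA exactly).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct AdexParams {
  double C, gL, EL, VT, DeltaT, Vreset, Vcut, tref_ms;
  double a, b, tauw_ms;
  double gh, Eh, Vh, kh, tauh_ms;
};

static AdexParams unpack_params(const List& p) {
  AdexParams q;
  q.C = as<double>(p["C_pF"]);
  q.gL = as<double>(p["gL_nS"]);
  q.EL = as<double>(p["EL_mV"]);
  q.VT = as<double>(p["VT_mV"]);
  q.DeltaT = as<double>(p["DeltaT_mV"]);
  q.Vreset = as<double>(p["Vreset_mV"]);
  q.Vcut = as<double>(p["Vcut_mV"]);
  q.tref_ms = as<double>(p["tref_ms"]);
  q.a = as<double>(p["a_nS"]);
  q.b = as<double>(p["b_pA"]);
  q.tauw_ms = as<double>(p["tauw_ms"]);
  q.gh = as<double>(p["gh_nS"]);
  q.Eh = as<double>(p["Eh_mV"]);
  q.Vh = as<double>(p["Vh_mV"]);
  q.kh = as<double>(p["kh_mV"]);
  q.tauh_ms = as<double>(p["tauh_ms"]);
  return q;
}

struct AdexState { double V, w, h; };

// One dt step. Returns true when a spike is emitted at the end of the step.
static inline bool adex_step(const AdexParams& q, AdexState& s, double I_pA,
                             double dt, int& ref_steps) {
  double hinf = 1.0 / (1.0 + std::exp((s.V - q.Vh) / q.kh));
  double h_new = hinf + (s.h - hinf) * std::exp(-dt / q.tauh_ms);
  double wtarg = q.a * (s.V - q.EL);
  double w_new = wtarg + (s.w - wtarg) * std::exp(-dt / q.tauw_ms);

  if (ref_steps > 0) {            // voltage clamped at reset during refractory
    --ref_steps;
    s.h = h_new; s.w = w_new;
    s.V = q.Vreset;
    return false;
  }

  double ex = 0.0;
  if (q.DeltaT > 0.0) {
    double arg = (s.V - q.VT) / q.DeltaT;
    double cap = (q.Vcut - q.VT) / q.DeltaT;  // overflow guard
    if (arg > cap) arg = cap;
    ex = q.gL * q.DeltaT * std::exp(arg);
  }
  double g = q.gL + q.gh * s.h;
  double Vinf = (q.gL * q.EL + q.gh * s.h * q.Eh + I_pA - s.w + ex) / g;
  double V_new = Vinf + (s.V - Vinf) * std::exp(-dt * g / q.C);

  s.h = h_new; s.w = w_new;
  if (!std::isfinite(V_new))
    stop("membrane potential became non-finite (unstable integration)");
  if (V_new >= q.Vcut) {
    s.V = q.Vreset;
    s.w += q.b;
    ref_steps = (int) std::lround(q.tref_ms / dt);
    return true;
  }
  s.V = V_new;
  return false;
}

// Settle at I = 0 from (EL, 0, hinf(EL)); returns c(V, w, h).
// [[Rcpp::export]]
NumericVector adex_settle_cpp(List params, double dt_ms, double settle_ms) {
  AdexParams q = unpack_params(params);
  AdexState s;
  s.V = q.EL;
  s.w = 0.0;
  s.h = 1.0 / (1.0 + std::exp((q.EL - q.Vh) / q.kh));
  int ref = 0;
  int n = (int) std::lround(settle_ms / dt_ms);
  for (int i = 0; i < n; ++i) adex_step(q, s, 0.0, dt_ms, ref);
  return NumericVector::create(s.V, s.w, s.h);
}

// Simulate one square-pulse sweep from a given initial state.
// Returns voltage sampled every `out_every` fine steps (spike samples
// stylized to Vcut) and the exact fine-grid spike times in ms.
// [[Rcpp::export]]
List adex_sweep_cpp(List params, NumericVector state0, double amp_pA,
                    double pre_ms, double step_ms, double post_ms,
                    double dt_ms, int out_every,
                    double noise_sigma_pA, double noise_tau_ms) {
  AdexParams q = unpack_params(params);
  AdexState s;
  s.V = state0[0]; s.w = state0[1]; s.h = state0[2];

  int n_fine = (int) std::lround((pre_ms + step_ms + post_ms) / dt_ms);
  int i_on  = (int) std::lround(pre_ms / dt_ms);
  int i_off = (int) std::lround((pre_ms + step_ms) / dt_ms);
  int n_out = n_fine / out_every + 1;

  NumericVector v_out(n_out);
  std::vector<double> spikes;
  int ref = 0;

  bool noisy = noise_sigma_pA > 0.0;
  double Inoise = 0.0, e_n = 0.0, s_n = 0.0;
  if (noisy) {
    e_n = std::exp(-dt_ms / noise_tau_ms);
    s_n = noise_sigma_pA * std::sqrt(1.0 - e_n * e_n);
  }

  v_out[0] = s.V;
  for (int i = 0; i < n_fine; ++i) {
    double I = (i >= i_on && i < i_off) ? amp_pA : 0.0;
    if (noisy) {
      Inoise = Inoise * e_n + s_n * norm_rand();
      I += Inoise;
    }
    bool sp = adex_step(q, s, I, dt_ms, ref);
    if (sp) spikes.push_back((i + 1) * dt_ms);
    if ((i + 1) % out_every == 0) v_out[(i + 1) / out_every] = s.V;
  }

  // stylized spike marker: nearest output sample set to the cutoff voltage
  for (size_t k = 0; k < spikes.size(); ++k) {
    int j = (int) std::lround(spikes[k] / (dt_ms * out_every));
    if (j >= 0 && j < n_out) v_out[j] = q.Vcut;
  }

  return List::create(_["voltage_mV"] = v_out,
                      _["spike_times_ms"] = wrap(spikes));
}

// Spike count for a constant step of step_ms from state0 (noise off);
// cheap kernel for rheobase bisection.
// [[Rcpp::export]]
int adex_count_spikes_cpp(List params, NumericVector state0, double amp_pA,
                          double step_ms, double dt_ms) {
  AdexParams q = unpack_params(params);
  AdexState s;
  s.V = state0[0]; s.w = state0[1]; s.h = state0[2];
  int n = (int) std::lround(step_ms / dt_ms);
  int ref = 0, count = 0;
  for (int i = 0; i < n; ++i)
    if (adex_step(q, s, amp_pA, dt_ms, ref)) ++count;
  return count;
}
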