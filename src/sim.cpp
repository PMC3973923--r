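#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Internal unit system: mV, ms, nS, pA, pF.  Consistency: nS*mV = pA and
// pF*mV/ms = pA, so no conversion factors appear anywhere.

struct ModelParams {
  double C, gL, VL, gNa, gK, gAHP, ENa, EK;
};

static ModelParams unpack_params(const List& p) {
  ModelParams P;
  P.C    = as<double>(p["C_pF"]);
  P.gL   = as<double>(p["G_leak_nS"]);
  P.VL   = as<double>(p["V_rest_mV"]);
  P.gNa  = as<double>(p["gbar_Na_nS"]);
  P.gK   = as<double>(p["gbar_K_nS"]);
  P.gAHP = as<double>(p["gbar_AHP_nS"]);
  P.ENa  = as<double>(p["E_Na_mV"]);
  P.EK   = as<double>(p["E_K_mV"]);
  return P;
}

// x / (1 - exp(-x/y)), stable through the removable singularity at x = 0
static inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 + 0.5 * r);
  return x / (1.0 - std::exp(-r));
}

// Exact exponential relaxation of each first-order gate over one step,
// holding V fixed (rates in 1/ms; temperature factor folded in).
static inline void advance_gates(double V, double dt,
                                 double& m, double& h, double& n, double& w) {
  double am = 0.5  * vtrap(V + 44.0, 10.0);
  double bm = 20.0 * std::exp(-(V + 60.0) / 18.0);
  double an = 0.04 * vtrap(V + 34.0, 10.0);
  double bn = 0.5  * std::exp(-(V + 44.0) / 80.0);

  double tm = 1.0 / (am + bm), minf = am * tm;
  double tn = 1.0 / (an + bn), ninf = an * tn;
  // steep Na inactivation, well separated from activation so no window
  // current can latch the cell depolarized; recovery is fast enough at the
  // -75 mV reset for full de-inactivation between 200 Hz probe cycles
  double hinf = 0.007 + 0.993 / (1.0 + std::exp((V + 55.0) / 10.0));
  double th = 0.2 + 2.5 / (1.0 + std::exp((V + 65.0) / 12.0));
  m = minf + (m - minf) * std::exp(-dt / tm);
  h = hinf + (h - hinf) * std::exp(-dt / th);
  n = ninf + (n - ninf) * std::exp(-dt / tn);

  double winf = 1.0 / (1.0 + std::exp(-(V + 25.0) / 5.0));
  const double tauw = 30.0;
  w = winf + (w - winf) * std::exp(-dt / tauw);
}

// One voltage step by exponential integration of the (gate-frozen) linear
// membrane equation.  Gc/Vc is an extra conductance term (dynamic-clamp
// injection), Iconst the voltage-independent current over the step.
static inline double advance_V(const ModelParams& P, double V,
                               double m, double h, double n, double w,
                               double Gc, double Vc, double Iconst, double dt) {
  double gna = P.gNa * m * m * m * h;
  double gk  = P.gK * n * n * n * n;
  double gah = P.gAHP * w;
  double Gtot = P.gL + gna + gk + gah + Gc;
  double num  = P.gL * P.VL + gna * P.ENa + (gk + gah) * P.EK + Gc * Vc + Iconst;
  double Vinf = num / Gtot;
  return Vinf + (V - Vinf) * std::exp(-dt * Gtot / P.C);
}

static void check_finite(double V, double m, double h, double n, double w,
                         int i) {
  if (!std::isfinite(V)) stop("non-finite membrane voltage V at step %d", i);
  if (!std::isfinite(m)) stop("non-finite gating variable m at step %d", i);
  if (!std::isfinite(h)) stop("non-finite gating variable h at step %d", i);
  if (!std::isfinite(n)) stop("non-finite gating variable n at step %d", i);
  if (!std::isfinite(w)) stop("non-finite gating variable w at step %d", i);
}

// [[Rcpp::export(name = ".fc_model_step")]]
NumericVector fc_model_step(List params, NumericVector state, double I_inj,
                            double dt) {
  ModelParams P = unpack_params(params);
  double V = state[0], m = state[1], h = state[2], n = state[3], w = state[4];
  advance_gates(V, dt, m, h, n, w);
  V = advance_V(P, V, m, h, n, w, 0.0, 0.0, I_inj, dt);
  check_finite(V, m, h, n, w, 0);
  return NumericVector::create(V, m, h, n, w);
}

// [[Rcpp::export(name = ".fc_gate_inf")]]
NumericVector fc_gate_inf(double V) {
  double m = 0, h = 0, n = 0, w = 0;
  // one very long "step" relaxes each gate to its steady state at V
  advance_gates(V, 1e9, m, h, n, w);
  return NumericVector::create(m, h, n, w);
}

// Closed-loop fixed-step simulation.  Optional meander state machine
// (POSITIVE for tau_plus, NEGATIVE until the first sample with
// V <= V_reset or the safety cap, then ZERO until the next cycle start)
// plus dynamic-clamp injection of per-step control signals (I, G) about V0.
// The controller is sample-and-hold: all currents for step i are computed
// from the recorded voltage at the start of step i.
// [[Rcpp::export(name = ".fc_simulate")]]
List fc_simulate(List params, double dt, int n_steps, NumericVector state0,
                 double I_hold, double V0,
                 bool meander_on, double rate, double I_plus, double I_minus,
                 double tau_plus, double V_reset, double tau_minus_max,
                 NumericVector ctrl_I, NumericVector ctrl_G) {
  ModelParams P = unpack_params(params);
  bool have_ctrl = ctrl_I.size() > 0;
  if (have_ctrl && (ctrl_I.size() < n_steps || ctrl_G.size() < n_steps))
    stop("control signals shorter than the simulation");

  NumericVector V_out(n_steps), I_out(n_steps);
  double V = state0[0], m = state0[1], h = state0[2], n_ = state0[3],
         w = state0[4];

  // meander bookkeeping (all in step indices to avoid float drift)
  double period = meander_on ? 1000.0 / rate : 0.0;
  long long s_k = 0, s_next = 0, p_k = 0;
  long long tau_plus_steps = meander_on ? llround(tau_plus / dt) : 0;
  long long cap_steps = meander_on ? llround(tau_minus_max / dt) : 0;
  int k = -1;                 // current cycle index
  bool neg_active = false;
  std::vector<long long> mk_start, mk_pulse_end, mk_neg_end, mk_end;
  std::vector<int> mk_term;

  for (int i = 0; i < n_steps; ++i) {
    double Im = 0.0;
    if (meander_on) {
      if ((k < 0 || i >= (int)s_next)) {
        long long cand_start = (k < 0) ? 0 : s_next;
        long long cand_next = llround((double)((k < 0 ? 0 : k + 1) + 1) * period / dt);
        if (cand_next <= (long long)n_steps) {  // full cycle fits
          if (k >= 0 && neg_active) {           // should not happen (cap < cycle)
            mk_neg_end.back() = i; mk_term.back() = 2;
          }
          ++k;
          s_k = cand_start; s_next = cand_next; p_k = s_k + tau_plus_steps;
          neg_active = false;
          mk_start.push_back(s_k);
          mk_pulse_end.push_back(p_k);
          mk_neg_end.push_back(-1);
          mk_end.push_back(s_next);
          mk_term.push_back(0);
        }
      }
      if (k >= 0 && i >= (int)s_k && i < (int)s_next) {
        if (i < (int)p_k) {
          Im = I_plus;
        } else if (i == (int)p_k) {
          neg_active = true;
          Im = I_minus;
        } else if (neg_active) {
          if (V <= V_reset) {
            neg_active = false;
            mk_neg_end[k] = i; mk_term[k] = 1;   // voltage crossing
            Im = 0.0;
          } else if (i - p_k >= cap_steps) {
            neg_active = false;
            mk_neg_end[k] = i; mk_term[k] = 2;   // safety cap
            Im = 0.0;
          } else {
            Im = I_minus;
          }
        }
      }
    }

    double Ic = 0.0, Gc = 0.0;
    if (have_ctrl) { Ic = ctrl_I[i]; Gc = ctrl_G[i]; }

    V_out[i] = V;
    I_out[i] = Im + I_hold + Ic - Gc * (V - V0);

    double Iconst = Im + I_hold + Ic;
    advance_gates(V, dt, m, h, n_, w);
    V = advance_V(P, V, m, h, n_, w, Gc, V0, Iconst, dt);
    if (i % 256 == 0) check_finite(V, m, h, n_, w, i);
  }
  check_finite(V, m, h, n_, w, n_steps);

  int ncyc = (int)mk_start.size();
  IntegerVector c_start(ncyc), c_pe(ncyc), c_ne(ncyc), c_end(ncyc), c_term(ncyc);
  for (int j = 0; j < ncyc; ++j) {
    c_start[j] = (int)mk_start[j] + 1;     // 1-based sample indices for R
    c_pe[j] = (int)mk_pulse_end[j] + 1;
    c_ne[j] = mk_neg_end[j] < 0 ? NA_INTEGER : (int)mk_neg_end[j] + 1;
    c_end[j] = (int)mk_end[j];             // last sample of the cycle (1-based)
    c_term[j] = mk_term[j];
  }
  return List::create(
    _["V"] = V_out, _["I_inj"] = I_out,
    _["state"] = NumericVector::create(V, m, h, n_, w),
    _["cycle_start"] = c_start, _["pulse_end"] = c_pe,
    _["neg_end"] = c_ne, _["cycle_end"] = c_end, _["terminated_by"] = c_term);
}
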