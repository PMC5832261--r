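// ten Tusscher-Panfilov 2006 human ventricular myocyte model and the
// beat-by-beat pacing driver.
//
// State vector layout (19 entries, fixed order, mirrored in R/cell_model.R):
//   0 V      membrane potential (mV)
//   1 Xr1    I_Kr activation
//   2 Xr2    I_Kr inactivation
//   3 Xs     I_Ks activation
//   4 m      I_Na activation
//   5 h      I_Na fast inactivation
//   6 j      I_Na slow inactivation
//   7 d      I_CaL activation
//   8 f      I_CaL voltage inactivation (slow)
//   9 f2     I_CaL voltage inactivation (fast)
//  10 fCass  I_CaL Ca-dependent inactivation
//  11 s      I_to inactivation
//  12 r      I_to activation
//  13 Cai    cytosolic free Ca2+ (mM)
//  14 CaSR   sarcoplasmic-reticulum free Ca2+ (mM)
//  15 Cass   dyadic-subspace free Ca2+ (mM)
//  16 Rq     SR release gate (fraction of available RyR)
//  17 Nai    intracellular Na+ (mM)
//  18 Ki     intracellular K+ (mM)
//
// Integration: Rush-Larsen exponential update for the 12 Hodgkin-Huxley
// gates and the (linear in its state) SR release gate, forward Euler for V
// and the concentrations, at a fixed step (default 0.02 ms) -- the scheme
// used for this model since its original publication. Fully deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct P {
  double R, T, F, Cm, Vc, Vsr, Vss;
  double Ko, Nao, Cao;
  double gNa, gK1, gto, gKr, gKs, gCaL, gbNa, gbCa, gpK, gpCa;
  double pKNa, PNaK, KmK, KmNa, kNaCa, KmNai, KmCa, ksat, alpha_ncx, gamma_ncx;
  double KpCa;
  double Vmaxup, Kup, Vrel, k1p, k2p, k3, k4, EC, maxsr, minsr, Vleak, Vxfer;
  double Bufc, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
};

static P read_params(const List& pl) {
  P p;
  p.R = pl["R"]; p.T = pl["T"]; p.F = pl["F"];
  p.Cm = pl["Cm"]; p.Vc = pl["V_c"]; p.Vsr = pl["V_sr"]; p.Vss = pl["V_ss"];
  p.Ko = pl["K_o"]; p.Nao = pl["Na_o"]; p.Cao = pl["Ca_o"];
  p.gNa = pl["g_Na"]; p.gK1 = pl["g_K1"]; p.gto = pl["g_to"];
  p.gKr = pl["g_Kr"]; p.gKs = pl["g_Ks"]; p.gCaL = pl["g_CaL"];
  p.gbNa = pl["g_bNa"]; p.gbCa = pl["g_bCa"]; p.gpK = pl["g_pK"]; p.gpCa = pl["g_pCa"];
  p.pKNa = pl["p_KNa"]; p.PNaK = pl["P_NaK"]; p.KmK = pl["K_mK"]; p.KmNa = pl["K_mNa"];
  p.kNaCa = pl["k_NaCa"]; p.KmNai = pl["K_mNai"]; p.KmCa = pl["K_mCa"];
  p.ksat = pl["k_sat"]; p.alpha_ncx = pl["alpha_ncx"]; p.gamma_ncx = pl["gamma_ncx"];
  p.KpCa = pl["K_pCa"];
  p.Vmaxup = pl["V_maxup"]; p.Kup = pl["K_up"]; p.Vrel = pl["V_rel"];
  p.k1p = pl["k1_prime"]; p.k2p = pl["k2_prime"]; p.k3 = pl["k3"]; p.k4 = pl["k4"];
  p.EC = pl["EC"]; p.maxsr = pl["max_sr"]; p.minsr = pl["min_sr"];
  p.Vleak = pl["V_leak"]; p.Vxfer = pl["V_xfer"];
  p.Bufc = pl["Buf_c"]; p.Kbufc = pl["K_bufc"];
  p.Bufsr = pl["Buf_sr"]; p.Kbufsr = pl["K_bufsr"];
  p.Bufss = pl["Buf_ss"]; p.Kbufss = pl["K_bufss"];
  return p;
}

// Voltage-only replacement of a gated current (time-dependence removal):
// polynomial in V over [vmin, vmax], held at the boundary value outside.
struct Clamp {
  int which;                 // 0 = I_CaL, 1 = I_Kr, 2 = I_Ks
  std::vector<double> coef;  // low -> high degree, in (v - vc)/vs
  double vmin, vmax, blank;  // mV, mV, ms after upstroke
  double vc, vs;             // centering/scaling of the polynomial basis
  double eval(double v) const {
    if (v < vmin) v = vmin;
    if (v > vmax) v = vmax;
    const double u = (v - vc) / vs;
    double acc = 0.0;
    for (int k = (int)coef.size() - 1; k >= 0; --k) acc = acc * u + coef[k];
    return acc;
  }
};

static std::vector<Clamp> read_clamps(const List& cl) {
  std::vector<Clamp> out;
  for (int i = 0; i < cl.size(); ++i) {
    List c = cl[i];
    Clamp cc;
    std::string nm = as<std::string>(c["current"]);
    cc.which = (nm == "ICaL") ? 0 : (nm == "IKr") ? 1 : 2;
    cc.coef = as<std::vector<double> >(c["coefficients"]);
    NumericVector vr = c["v_range"];
    cc.vmin = vr[0]; cc.vmax = vr[1];
    cc.blank = as<double>(c["blank_ms"]);
    cc.vc = as<double>(c["v_center"]);
    cc.vs = as<double>(c["v_scale"]);
    out.push_back(cc);
  }
  return out;
}

// Full evaluation at one state: time-derivatives for the Euler states,
// steady-state values and time constants for the Rush-Larsen states, and
// the three clampable currents (native values).
// gate order: 0 Xr1 1 Xr2 2 Xs 3 m 4 h 5 j 6 d 7 f 8 f2 9 fCass 10 s 11 r 12 Rq
struct Eval {
  double dV, dCai, dCaSR, dCass, dNai, dKi;
  double ginf[13], gtau[13];
  double ICaL, IKr, IKs;
};

static inline void tp06_eval(const double* y, const P& p, double istim,
                             const std::vector<Clamp>& clamps,
                             const bool* clamp_on, Eval& e) {
  const double V = y[0];
  const double Xr1 = y[1], Xr2 = y[2], Xs = y[3];
  const double m = y[4], h = y[5], j = y[6];
  const double d = y[7], f = y[8], f2 = y[9], fCass = y[10];
  const double s = y[11], r = y[12];
  const double Cai = y[13], CaSR = y[14], Cass = y[15], Rq = y[16];
  const double Nai = y[17], Ki = y[18];

  const double RTF = p.R * p.T / p.F;
  const double EK  = RTF * std::log(p.Ko / Ki);
  const double ENa = RTF * std::log(p.Nao / Nai);
  const double EKs = RTF * std::log((p.Ko + p.pKNa * p.Nao) / (Ki + p.pKNa * Nai));
  const double ECa = 0.5 * RTF * std::log(p.Cao / Cai);

  const double INa = p.gNa * m * m * m * h * j * (V - ENa);

  double ICaL;
  {
    const double z = 2.0 * (V - 15.0) / RTF;  // zF(V-15)/RT with z_Ca = 2
    const double gate = p.gCaL * d * f * f2 * fCass;
    if (std::fabs(z) > 1e-5) {
      ICaL = gate * 4.0 * (V - 15.0) * p.F * p.F / (p.R * p.T) *
             (0.25 * Cass * std::exp(z) - p.Cao) / (std::exp(z) - 1.0);
    } else {
      // limit V -> 15 mV of the GHG flux expression
      ICaL = gate * 2.0 * p.F * (0.25 * Cass - p.Cao);
    }
  }

  const double Ito = p.gto * r * s * (V - EK);
  const double IKr = p.gKr * std::sqrt(p.Ko / 5.4) * Xr1 * Xr2 * (V - EK);
  const double IKs = p.gKs * Xs * Xs * (V - EKs);

  const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                      std::exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - EK)));
  const double IK1 = p.gK1 * std::sqrt(p.Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  const double VFRT = V / RTF;
  const double INaCa = p.kNaCa *
      (std::exp(p.gamma_ncx * VFRT) * Nai * Nai * Nai * p.Cao -
       std::exp((p.gamma_ncx - 1.0) * VFRT) * p.Nao * p.Nao * p.Nao * Cai * p.alpha_ncx) /
      ((p.KmNai * p.KmNai * p.KmNai + p.Nao * p.Nao * p.Nao) * (p.KmCa + p.Cao) *
       (1.0 + p.ksat * std::exp((p.gamma_ncx - 1.0) * VFRT)));

  const double INaK = p.PNaK * p.Ko * Nai /
      ((p.Ko + p.KmK) * (Nai + p.KmNa) *
       (1.0 + 0.1245 * std::exp(-0.1 * VFRT) + 0.0353 * std::exp(-VFRT)));

  const double IpCa = p.gpCa * Cai / (Cai + p.KpCa);
  const double IpK  = p.gpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = p.gbNa * (V - ENa);
  const double IbCa = p.gbCa * (V - ECa);

  e.ICaL = ICaL; e.IKr = IKr; e.IKs = IKs;
  // active clamps substitute the value used in the charge balance (and, for
  // I_CaL, in the subspace Ca2+ flux)
  double uCaL = ICaL, uKr = IKr, uKs = IKs;
  for (size_t ci = 0; ci < clamps.size(); ++ci) {
    if (!clamp_on[ci]) continue;
    const double val = clamps[ci].eval(V);
    if (clamps[ci].which == 0) uCaL = val;
    else if (clamps[ci].which == 1) uKr = val;
    else uKs = val;
  }

  const double Iion = IK1 + Ito + uKr + uKs + uCaL + INaK + INa + IbNa +
                      INaCa + IbCa + IpK + IpCa;
  e.dV = -(Iion + istim);

  // SR calcium handling
  const double kcasr = p.maxsr - (p.maxsr - p.minsr) /
                       (1.0 + (p.EC / CaSR) * (p.EC / CaSR));
  const double k1 = p.k1p / kcasr;
  const double k2 = p.k2p * kcasr;
  const double O = k1 * Cass * Cass * Rq / (p.k3 + k1 * Cass * Cass);
  const double Irel  = p.Vrel * O * (CaSR - Cass);
  const double Ileak = p.Vleak * (CaSR - Cai);
  const double Iup   = p.Vmaxup / (1.0 + (p.Kup / Cai) * (p.Kup / Cai));
  const double Ixfer = p.Vxfer * (Cass - Cai);

  { // release gate: dRq/dt = k4 (1 - Rq) - k2 Cass Rq
    const double rate = p.k4 + k2 * Cass;
    e.ginf[12] = p.k4 / rate;
    e.gtau[12] = 1.0 / rate;
  }

  const double bufc  = 1.0 / (1.0 + p.Bufc * p.Kbufc /
                      ((Cai + p.Kbufc) * (Cai + p.Kbufc)));
  const double bufsr = 1.0 / (1.0 + p.Bufsr * p.Kbufsr /
                      ((CaSR + p.Kbufsr) * (CaSR + p.Kbufsr)));
  const double bufss = 1.0 / (1.0 + p.Bufss * p.Kbufss /
                      ((Cass + p.Kbufss) * (Cass + p.Kbufss)));

  e.dCai  = bufc * ((Ileak - Iup) * p.Vsr / p.Vc + Ixfer -
                    (IbCa + IpCa - 2.0 * INaCa) * p.Cm / (2.0 * p.Vc * p.F));
  e.dCaSR = bufsr * (Iup - Irel - Ileak);
  e.dCass = bufss * (-uCaL * p.Cm / (2.0 * p.Vss * p.F) +
                     Irel * p.Vsr / p.Vss - Ixfer * p.Vc / p.Vss);
  e.dNai = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * p.Cm / (p.Vc * p.F);
  e.dKi  = -(IK1 + Ito + uKr + uKs + IpK + istim - 2.0 * INaK) * p.Cm / (p.Vc * p.F);

  // gate kinetics (steady state, tau in ms)
  { // Xr1
    const double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    e.ginf[0] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    e.gtau[0] = a * b;
  }
  { // Xr2
    const double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    e.ginf[1] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    e.gtau[1] = a * b;
  }
  { // Xs
    const double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    const double b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    e.ginf[2] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    e.gtau[2] = a * b + 80.0;
  }
  { // m
    const double q = 1.0 + std::exp((-56.86 - V) / 9.03);
    const double a = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double b = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                     0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    e.ginf[3] = 1.0 / (q * q);
    e.gtau[3] = a * b;
  }
  { // h
    const double q = 1.0 + std::exp((V + 71.55) / 7.43);
    double a, b;
    if (V < -40.0) {
      a = 0.057 * std::exp(-(V + 80.0) / 6.8);
      b = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    } else {
      a = 0.0;
      b = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    }
    e.ginf[4] = 1.0 / (q * q);
    e.gtau[4] = 1.0 / (a + b);
  }
  { // j (same steady state as h)
    double a, b;
    if (V < -40.0) {
      a = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
          (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      b = 0.02424 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
    } else {
      a = 0.0;
      b = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    }
    e.ginf[5] = e.ginf[4];
    e.gtau[5] = 1.0 / (a + b);
  }
  { // d
    const double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double g = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    e.ginf[6] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    e.gtau[6] = a * b + g;
  }
  { // f
    e.ginf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    e.gtau[7] = 1102.5 * std::exp(-((V + 27.0) * (V + 27.0)) / 225.0) +
                200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  }
  { // f2
    e.ginf[8] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    e.gtau[8] = 562.0 * std::exp(-((V + 27.0) * (V + 27.0)) / 240.0) +
                31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  }
  { // fCass (depends on subspace Ca2+, not V)
    const double x = Cass / 0.05;
    e.ginf[9] = 0.6 / (1.0 + x * x) + 0.4;
    e.gtau[9] = 80.0 / (1.0 + x * x) + 2.0;
  }
  { // s (epicardial formulation)
    e.ginf[10] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    e.gtau[10] = 85.0 * std::exp(-((V + 45.0) * (V + 45.0)) / 320.0) +
                 5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  { // r
    e.ginf[11] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    e.gtau[11] = 9.5 * std::exp(-((V + 40.0) * (V + 40.0)) / 1800.0) + 0.8;
  }
}

static const int GATE_IDX[13] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 16};

// [[Rcpp::export]]
NumericVector tp06_rhs_cpp(NumericVector y, List params, double i_stim,
                           List clamps, LogicalVector clamps_active) {
  if (y.size() != 19) stop("state vector must have 19 entries");
  for (int i = 0; i < 19; ++i)
    if (!R_finite(y[i])) stop("non-finite state entry at position %d", i + 1);
  P p = read_params(params);
  std::vector<Clamp> cl = read_clamps(clamps);
  bool on[16];
  for (int i = 0; i < 16; ++i) on[i] = false;
  for (size_t i = 0; i < cl.size() && i < 16; ++i)
    on[i] = (i < (size_t)clamps_active.size()) ? (bool)clamps_active[i] : true;
  Eval e;
  tp06_eval(REAL(y), p, i_stim, cl, on, e);
  NumericVector dy(19);
  dy[0] = e.dV;
  for (int g = 0; g < 13; ++g) {
    const int si = GATE_IDX[g];
    dy[si] = (e.ginf[g] - y[si]) / e.gtau[g];
  }
  dy[13] = e.dCai; dy[14] = e.dCaSR; dy[15] = e.dCass;
  dy[17] = e.dNai; dy[18] = e.dKi;
  return dy;
}

// [[Rcpp::export]]
NumericVector tp06_currents_cpp(NumericVector y, List params) {
  P p = read_params(params);
  std::vector<Clamp> cl;
  bool on[1] = {false};
  Eval e;
  tp06_eval(REAL(y), p, 0.0, cl, on, e);
  return NumericVector::create(_["ICaL"] = e.ICaL, _["IKr"] = e.IKr,
                               _["IKs"] = e.IKs, _["dVdt"] = e.dV);
}

// Drive the model through a stimulus sequence.
//
// stim_times   absolute onset times (ms), strictly increasing
// stim_enabled per-stimulus flag (a disabled entry keeps its slot/index)
// total_ms     total integration time
//
// Per-beat outputs: upstroke time (quadratically refined argmax dV/dt within
// 20 ms of the stimulus onset), APD to the interpolated downward -60 mV
// crossing, capture flag (V exceeded 0 mV within the window with a genuine
// upstroke), merged-beat flag (next stimulus arrived before repolarization).
// Snapshots are the full state immediately before each stimulus onset.
// [[Rcpp::export]]
List tp06_run_cpp(NumericVector y0, List params,
                  NumericVector stim_times, LogicalVector stim_enabled,
                  double total_ms, double stim_amp, double stim_dur,
                  double dt, List clamps_, bool record_trace, double trace_dt,
                  bool record_states) {
  if (y0.size() != 19) stop("state vector must have 19 entries");
  for (int i = 0; i < 19; ++i)
    if (!R_finite(y0[i])) stop("non-finite state entry at position %d", i + 1);
  P p = read_params(params);
  std::vector<Clamp> clamps = read_clamps(clamps_);
  const size_t ncl = clamps.size();
  if (ncl > 16) stop("at most 16 simultaneous clamps supported");
  bool clamp_on[16];

  const int nb = stim_times.size();
  const long nsteps = (long)std::llround(total_ms / dt);
  std::vector<long> stim_step(nb);
  for (int i = 0; i < nb; ++i) stim_step[i] = (long)std::llround(stim_times[i] / dt);
  const long dur_steps = std::max(1L, (long)std::llround(stim_dur / dt));
  const long win_steps = (long)std::llround(20.0 / dt);

  double y[19];
  for (int i = 0; i < 19; ++i) y[i] = y0[i];

  NumericVector upstroke(nb, NA_REAL), apd(nb, NA_REAL);
  LogicalVector captured(nb), merged(nb);
  NumericMatrix states(record_states ? nb : 0, record_states ? 19 : 1);
  const long trace_stride = record_trace ? std::max(1L, (long)std::llround(trace_dt / dt)) : 1;
  const long ntr = record_trace ? nsteps / trace_stride + 2 : 1;
  NumericMatrix trace(record_trace ? ntr : 1, 6);
  long tr_row = 0;

  int next_stim = 0;            // next stimulus slot not yet opened
  int cur_stim = -1;            // stimulus with an open 20-ms capture window
  long win_end = -1;
  double best_dvdt = -1e300, best_t = 0.0, best_prev = 0.0, best_next = 0.0;
  long best_step = -1;
  bool want_next = false;
  bool window_crossed0 = false;
  bool onset_excitable = true;
  int ap_beat = -1;             // beat whose AP awaits the -60 mV crossing
  double ap_upstroke = 0.0;
  // clamps suspended (native gating) from stimulus onset to upstroke + blank
  double clamp_resume[16];
  for (size_t i = 0; i < 16; ++i) clamp_resume[i] = -1e300;

  double dvdt_prev = 0.0;
  Eval e;

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    while (next_stim < nb && stim_step[next_stim] == step) {
      if (record_states)
        for (int i = 0; i < 19; ++i) states(next_stim, i) = y[i];
      cur_stim = next_stim;
      win_end = step + win_steps;
      best_dvdt = -1e300; best_step = -1; want_next = false;
      window_crossed0 = false;
      // capture requires a genuine regenerative upstroke: V must start below
      // 0 mV (a stimulus landing on an ongoing plateau is not a new beat)
      onset_excitable = (y[0] < 0.0);
      if (stim_enabled[cur_stim])
        for (size_t ci = 0; ci < ncl; ++ci) clamp_resume[ci] = R_PosInf;
      ++next_stim;
    }

    double istim = 0.0;
    if (cur_stim >= 0 && stim_enabled[cur_stim]) {
      const long ss = stim_step[cur_stim];
      if (step >= ss && step < ss + dur_steps) istim = -stim_amp;
    }

    for (size_t ci = 0; ci < ncl; ++ci) clamp_on[ci] = (t >= clamp_resume[ci]);

    tp06_eval(y, p, istim, clamps, clamp_on, e);

    if (record_trace && step % trace_stride == 0) {
      trace(tr_row, 0) = t; trace(tr_row, 1) = y[0]; trace(tr_row, 2) = e.dV;
      trace(tr_row, 3) = e.ICaL; trace(tr_row, 4) = e.IKr; trace(tr_row, 5) = e.IKs;
      ++tr_row;
    }

    // upstroke search within the open capture window
    if (cur_stim >= 0) {
      if (want_next && step == best_step + 1) { best_next = e.dV; want_next = false; }
      if (e.dV > best_dvdt) {
        best_dvdt = e.dV; best_t = t; best_step = step;
        best_prev = dvdt_prev; want_next = true;
      }
      if (y[0] > 0.0) window_crossed0 = true;
      if (step == win_end) {
        if (onset_excitable && window_crossed0 && best_dvdt > 10.0) {
          captured[cur_stim] = true;
          double tu = best_t;
          const double denom = best_prev - 2.0 * best_dvdt + best_next;
          if (denom < 0.0 && !want_next) {
            const double delta = 0.5 * (best_prev - best_next) / denom;
            if (std::fabs(delta) <= 1.0) tu += delta * dt;
          }
          upstroke[cur_stim] = tu;
          ap_beat = cur_stim;
          ap_upstroke = tu;
          for (size_t ci = 0; ci < ncl; ++ci)
            clamp_resume[ci] = tu + clamps[ci].blank;
        } else {
          // capture failure: clamps resume right away
          for (size_t ci = 0; ci < ncl; ++ci)
            if (!R_finite(clamp_resume[ci])) clamp_resume[ci] = t;
        }
        cur_stim = -1;
      }
    }

    // advance: forward Euler (V, concentrations), Rush-Larsen (gates)
    const double Vold = y[0];
    const double Vnew = Vold + dt * e.dV;
    y[13] += dt * e.dCai;
    y[14] += dt * e.dCaSR;
    y[15] += dt * e.dCass;
    y[17] += dt * e.dNai;
    y[18] += dt * e.dKi;
    for (int g = 0; g < 13; ++g) {
      const int si = GATE_IDX[g];
      y[si] = e.ginf[g] + (y[si] - e.ginf[g]) * std::exp(-dt / e.gtau[g]);
    }
    y[0] = Vnew;

    // downward -60 mV crossing closes the current AP
    if (ap_beat >= 0 && Vold >= -60.0 && Vnew < -60.0 && t > ap_upstroke + 1.0) {
      const double tcross = t + dt * (Vold + 60.0) / (Vold - Vnew);
      apd[ap_beat] = tcross - ap_upstroke;
      ap_beat = -1;
    }
    // merged beat: the next enabled stimulus fires before repolarization
    if (ap_beat >= 0 && next_stim < nb && stim_step[next_stim] == step + 1 &&
        stim_enabled[next_stim] && ap_beat != cur_stim) {
      merged[ap_beat] = true;
      ap_beat = -1;
    }

    dvdt_prev = e.dV;
    if (!R_finite(y[0]))
      stop("integration diverged at t = %.3f ms (beat %d)", t, next_stim);
  }

  NumericVector yfin(19);
  for (int i = 0; i < 19; ++i) yfin[i] = y[i];

  List out = List::create(
    _["upstroke_ms"] = upstroke, _["apd_ms"] = apd,
    _["captured"] = captured, _["merged"] = merged,
    _["final_state"] = yfin);
  if (record_states) out["states"] = states;
  if (record_trace) {
    if (tr_row < 1) tr_row = 1;
    out["trace"] = trace(Range(0, tr_row - 1), Range(0, 5));
  }
  return out;
}
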