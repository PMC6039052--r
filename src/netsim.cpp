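// Network integration core: fixed-step integration of thalamic (TC,
// RE) and cortical (PY, IN) cells with event-driven synapses,
// short-term depression, a GABA-B second-messenger cascade and Poisson
// miniature PSPs.
//
// Numerics: membrane voltages use a semi-implicit (backward-Euler in
// the conductances) update that is unconditionally stable; gating
// variables use exponential (Rush-Larsen) updates with steady state
// and time constant linearly interpolated from per-run lookup tables;
// the zero-capacitance axosomatic compartment is solved algebraically.
// Receptor open fractions are piecewise exponential between
// presynaptic events (the 0.3 ms transmitter pulse is applied as an
// instantaneous saturating increment at the event), which lets all
// synapses converging on a cell with the same receptor share one
// aggregated conductance state.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <random>
#include <vector>
#include "kinetics.h"

using namespace Rcpp;
using namespace spn;

// ---------------------------------------------------------------- tables

enum GateId {
  G_THAL_M, G_THAL_H, G_THAL_N, G_TCT_M, G_TCT_H, G_RET_M, G_RET_H,
  G_IH, G_CNA_M, G_CNA_H, G_KV, G_KM, G_HVA_M, G_HVA_H, NGATES
};

struct Tables {
  static const int NT = 3801;
  static constexpr double V0 = -130.0, DV = 0.05;
  std::vector<double> inf[NGATES], edt[NGATES], nmda;
  double dt;

  static Gate eval(int g, double v) {
    switch (g) {
      case G_THAL_M: return thal_na_m(v);
      case G_THAL_H: return thal_na_h(v);
      case G_THAL_N: return thal_k_n(v);
      case G_TCT_M:  return tc_it_m(v);
      case G_TCT_H:  return tc_it_h(v);
      case G_RET_M:  return re_it_m(v);
      case G_RET_H:  return re_it_h(v);
      case G_IH:     return ih_o(v);
      case G_CNA_M:  return cort_na_m(v);
      case G_CNA_H:  return cort_na_h(v);
      case G_KV:     return cort_kv_n(v);
      case G_KM:     return cort_km_n(v);
      case G_HVA_M:  return cort_hva_m(v);
      default:       return cort_hva_h(v);
    }
  }

  void build(double dt_, double nmda_vth, double nmda_delta) {
    dt = dt_;
    for (int g = 0; g < NGATES; ++g) {
      inf[g].resize(NT); edt[g].resize(NT);
      for (int i = 0; i < NT; ++i) {
        Gate k = eval(g, V0 + DV * i);
        inf[g][i] = k.inf;
        edt[g][i] = std::exp(-dt / k.tau);
      }
    }
    nmda.resize(NT);
    for (int i = 0; i < NT; ++i) {
      double v = V0 + DV * i;
      nmda[i] = 1.0 / (1.0 + std::exp(-(v - nmda_vth) / nmda_delta));
    }
  }

  inline void look(int g, double v, double& xinf, double& xedt) const {
    double u = (v - V0) / DV;
    if (u < 0) u = 0;
    if (u > NT - 1.001) u = NT - 1.001;
    int i = (int)u;
    double f = u - i;
    xinf = inf[g][i] + f * (inf[g][i + 1] - inf[g][i]);
    xedt = edt[g][i] + f * (edt[g][i + 1] - edt[g][i]);
  }
  inline double gate_nmda(double v) const {
    double u = (v - V0) / DV;
    if (u < 0) u = 0;
    if (u > NT - 1.001) u = NT - 1.001;
    int i = (int)u;
    double f = u - i;
    return nmda[i] + f * (nmda[i + 1] - nmda[i]);
  }
};

// ------------------------------------------------------------- parameters

struct ThalP {
  double Cm, g_leak, E_leak, g_KL, E_KL, g_Na, E_Na, g_K, E_K,
         g_T, g_h, E_h, tau_ca, ca_inf, vshift, ih_cac;
  bool is_tc;
};

struct CortP {
  double kappa_s, kappa_d, g_Na_s, g_K_s, g_Nap_s,
         Cm_d, g_L, E_leak, g_KL, E_KL, g_Na_d, g_Nap_d,
         g_HVA, g_KCa, g_Km, E_Na, E_K, tau_ca, ca_inf;
};

static double num(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

static ThalP thal_params(const List& p) {
  ThalP t;
  t.Cm = num(p, "Cm"); t.g_leak = num(p, "g_leak");
  t.E_leak = num(p, "E_leak"); t.g_KL = num(p, "g_KL");
  t.E_KL = num(p, "E_KL"); t.g_Na = num(p, "g_Na");
  t.E_Na = num(p, "E_Na"); t.g_K = num(p, "g_K");
  t.E_K = num(p, "E_K"); t.g_T = num(p, "g_T");
  t.g_h = num(p, "g_h"); t.E_h = num(p, "E_h");
  t.tau_ca = num(p, "tau_ca"); t.ca_inf = num(p, "ca_inf");
  t.vshift = num(p, "vtraub") - VTRAUB;  // offset from tabulated base
  t.ih_cac = p.containsElementNamed("ih_cac") ? num(p, "ih_cac")
                                              : IH_CAC;
  t.is_tc = as<std::string>(p["cell_class"]) == "TC";
  return t;
}

static CortP cort_params(const List& p) {
  CortP c;
  double r_axial = num(p, "r_axial");           // MOhm
  double g_c = 1e-3 / r_axial;                  // mS (0.1 uS at 10 MOhm)
  double S_soma = num(p, "S_soma");
  double R = num(p, "R");
  c.kappa_s = g_c / S_soma;                     // mS/cm2 on the soma
  c.kappa_d = g_c / (S_soma * R);               // mS/cm2 on the dendrite
  c.g_Na_s = num(p, "g_Na_s"); c.g_K_s = num(p, "g_K_s");
  c.g_Nap_s = num(p, "g_Nap_s");
  c.Cm_d = num(p, "Cm_d"); c.g_L = num(p, "g_L");
  c.E_leak = num(p, "E_leak"); c.g_KL = num(p, "g_KL");
  c.E_KL = num(p, "E_KL"); c.g_Na_d = num(p, "g_Na_d");
  c.g_Nap_d = num(p, "g_Nap_d"); c.g_HVA = num(p, "g_HVA");
  c.g_KCa = num(p, "g_KCa"); c.g_Km = num(p, "g_Km");
  c.E_Na = num(p, "E_Na"); c.E_K = num(p, "E_K");
  c.tau_ca = num(p, "tau_ca"); c.ca_inf = num(p, "ca_inf");
  return c;
}

// --------------------------------------------------------- cell stepping

// thalamic state slots
enum { TS_V, TS_M, TS_H, TS_N, TS_MT, TS_HT, TS_CA, TS_O1, TS_P1, TS_O2 };
// cortical state slots
enum { CS_VD, CS_VS, CS_MD, CS_HD, CS_MS, CS_HS, CS_NS, CS_KM, CS_KCA,
       CS_HVA_M, CS_HVA_H, CS_CA };

const int NSTATE = 12;  // per-cell state stride (thalamic cells use 10)

// one step of a thalamic cell; synG/synGE are the aggregate synaptic
// conductance and conductance*reversal sums; inj is injected current
// (uA/cm2, depolarizing positive)
static inline void thal_step(double* s, const ThalP& p, const Tables& T,
                             double dt, double synG, double synGE,
                             double inj, double eca) {
  double v = s[TS_V];
  double vna = v - p.vshift;  // per-class Traub threshold shift
  double xi, xe;
  T.look(G_THAL_M, vna, xi, xe); s[TS_M] = xi + (s[TS_M] - xi) * xe;
  T.look(G_THAL_H, vna, xi, xe); s[TS_H] = xi + (s[TS_H] - xi) * xe;
  T.look(G_THAL_N, vna, xi, xe); s[TS_N] = xi + (s[TS_N] - xi) * xe;
  T.look(p.is_tc ? G_TCT_M : G_RET_M, v, xi, xe);
  s[TS_MT] = xi + (s[TS_MT] - xi) * xe;
  T.look(p.is_tc ? G_TCT_H : G_RET_H, v, xi, xe);
  s[TS_HT] = xi + (s[TS_HT] - xi) * xe;

  double gT = p.g_T * s[TS_MT] * s[TS_MT] * s[TS_HT];
  double gh = 0.0;
  if (p.is_tc && p.g_h > 0) {
    T.look(G_IH, v, xi, xe);
    double target = xi * (1.0 - s[TS_O2]);
    s[TS_O1] = target + (s[TS_O1] - target) * xe;
    double ca = s[TS_CA];
    double r = ca / p.ih_cac;
    double k1ca = IH_K2 * r * r * r * r;
    // exact relaxation of the binding step (k1ca is unbounded in Ca)
    double pr = k1ca + IH_K2;
    double pinf = k1ca / pr;
    s[TS_P1] = pinf + (s[TS_P1] - pinf) * std::exp(-dt * pr);
    double k3p = IH_K4 * (s[TS_P1] / IH_PC);
    double flux = dt * (k3p * s[TS_O1] - IH_K4 * s[TS_O2]);
    s[TS_O1] -= flux; s[TS_O2] += flux;
    if (s[TS_O1] < 0) s[TS_O1] = 0;
    if (s[TS_O2] < 0) s[TS_O2] = 0;
    double tot = s[TS_O1] + s[TS_O2];
    if (tot > 1.0) { s[TS_O1] /= tot; s[TS_O2] /= tot; }
    gh = p.g_h * (s[TS_O1] + IH_GINC * s[TS_O2]);
  }
  double m = s[TS_M], h = s[TS_H], n = s[TS_N];
  double gNa = p.g_Na * m * m * m * h;
  double gK = p.g_K * n * n * n * n;

  double iT = gT * (v - eca);
  s[TS_CA] += dt * (-CA_DRIVE * iT +
                    (p.ca_inf - s[TS_CA]) / p.tau_ca);
  if (s[TS_CA] < 1e-8) s[TS_CA] = 1e-8;

  double G = p.g_leak + p.g_KL + gNa + gK + gT + gh + synG;
  double GE = p.g_leak * p.E_leak + p.g_KL * p.E_KL + gNa * p.E_Na +
              gK * p.E_K + gT * eca + gh * p.E_h + synGE;
  double a = dt / p.Cm;
  s[TS_V] = (v + a * (GE + inj)) / (1.0 + a * G);
}

// one step of a two-compartment cortical cell
static inline void cort_step(double* s, const CortP& p, const Tables& T,
                             double dt, double synG, double synGE,
                             double inj, double eca) {
  double vd = s[CS_VD], vs = s[CS_VS];
  double xi, xe;
  // dendritic gates
  T.look(G_CNA_M, vd, xi, xe); s[CS_MD] = xi + (s[CS_MD] - xi) * xe;
  T.look(G_CNA_H, vd, xi, xe); s[CS_HD] = xi + (s[CS_HD] - xi) * xe;
  T.look(G_KM, vd, xi, xe);    s[CS_KM] = xi + (s[CS_KM] - xi) * xe;
  T.look(G_HVA_M, vd, xi, xe); s[CS_HVA_M] = xi + (s[CS_HVA_M] - xi) * xe;
  T.look(G_HVA_H, vd, xi, xe); s[CS_HVA_H] = xi + (s[CS_HVA_H] - xi) * xe;
  // Ca-activated K+ gate (rates linear in [Ca], integrated directly)
  {
    double a = kca_alpha(s[CS_CA]), b = KCA_RB;
    s[CS_KCA] += dt * TADJ * (a * (1.0 - s[CS_KCA]) - b * s[CS_KCA]);
    if (s[CS_KCA] < 0) s[CS_KCA] = 0;
  }
  // somatic gates
  T.look(G_CNA_M, vs, xi, xe); s[CS_MS] = xi + (s[CS_MS] - xi) * xe;
  T.look(G_CNA_H, vs, xi, xe); s[CS_HS] = xi + (s[CS_HS] - xi) * xe;
  T.look(G_KV, vs, xi, xe);    s[CS_NS] = xi + (s[CS_NS] - xi) * xe;

  double gNad = p.g_Na_d * s[CS_MD] * s[CS_MD] * s[CS_MD] * s[CS_HD];
  double gNap_d = p.g_Nap_d * nap_minf(vd);
  double gHVA = p.g_HVA * s[CS_HVA_M] * s[CS_HVA_M] * s[CS_HVA_H];
  double gKCa = p.g_KCa * s[CS_KCA];
  double gKm = p.g_Km * s[CS_KM];

  double iHVA = gHVA * (vd - eca);
  s[CS_CA] += dt * (-CA_DRIVE * iHVA +
                    (p.ca_inf - s[CS_CA]) / p.tau_ca);
  if (s[CS_CA] < 1e-8) s[CS_CA] = 1e-8;

  double G = p.g_L + p.g_KL + gNad + gNap_d + gHVA + gKCa + gKm +
             p.kappa_d + synG;
  double GE = p.g_L * p.E_leak + p.g_KL * p.E_KL +
              (gNad + gNap_d) * p.E_Na + gHVA * eca +
              (gKCa + gKm) * p.E_K + p.kappa_d * vs + synGE;
  double a = dt / p.Cm_d;
  double vd_new = (vd + a * (GE + inj)) / (1.0 + a * G);
  s[CS_VD] = vd_new;

  // zero-capacitance axosomatic compartment: algebraic equilibrium of
  // its (conductance-form) currents with the axial current
  double gNas = p.g_Na_s * s[CS_MS] * s[CS_MS] * s[CS_MS] * s[CS_HS];
  double gKs = p.g_K_s * s[CS_NS];
  double gNaps = p.g_Nap_s * nap_minf(vs);
  s[CS_VS] = (p.kappa_s * vd_new + (gNas + gNaps) * p.E_Na +
              gKs * p.E_K) /
             (p.kappa_s + gNas + gNaps + gKs);
}

// -------------------------------------------------- synapse constants

struct SynConst {
  double a[3], b[3];       // AMPA, NMDA, GABA_A first-order rates
  double K1, K2, K3, K4, Kd;
  double T_amp, T_dur;
  double nmda_vth, nmda_delta;
  double dO_gain[3];       // 1 - exp(-(alpha T + beta) T_dur)
  double Oinf[3];          // alpha T / (alpha T + beta)
  double dR_gain, Rinf;    // GABA-B receptor pulse response
  void init(const NumericVector& v) {
    a[0] = v["ampa_alpha"]; b[0] = v["ampa_beta"];
    a[1] = v["nmda_alpha"]; b[1] = v["nmda_beta"];
    a[2] = v["gabaa_alpha"]; b[2] = v["gabaa_beta"];
    K1 = v["K1"]; K2 = v["K2"]; K3 = v["K3"]; K4 = v["K4"];
    Kd = v["Kd"];
    T_amp = v["T_amp"]; T_dur = v["T_dur"];
    nmda_vth = v["nmda_vth"]; nmda_delta = v["nmda_delta"];
    for (int r = 0; r < 3; ++r) {
      double k = a[r] * T_amp + b[r];
      dO_gain[r] = 1.0 - std::exp(-k * T_dur);
      Oinf[r] = a[r] * T_amp / k;
    }
    double kR = K1 * T_amp + K2;
    dR_gain = 1.0 - std::exp(-kR * T_dur);
    Rinf = K1 * T_amp / kR;
  }
};

// receptor codes
enum { R_AMPA = 0, R_NMDA = 1, R_GABAA = 2, R_GABAB = 3 };

// ------------------------------------------------------------- exports

// [[Rcpp::export]]
NumericVector thal_deriv_cpp(NumericVector state, List params,
                             double I_syn) {
  ThalP p = thal_params(params);
  const double* s = state.begin();
  double v = s[TS_V];
  NumericVector d(10);
  double vna = v - p.vshift;
  Gate gm = thal_na_m(vna), gh_ = thal_na_h(vna), gn = thal_k_n(vna);
  Gate gtm = p.is_tc ? tc_it_m(v) : re_it_m(v);
  Gate gth = p.is_tc ? tc_it_h(v) : re_it_h(v);
  d[TS_M] = (gm.inf - s[TS_M]) / gm.tau;
  d[TS_H] = (gh_.inf - s[TS_H]) / gh_.tau;
  d[TS_N] = (gn.inf - s[TS_N]) / gn.tau;
  d[TS_MT] = (gtm.inf - s[TS_MT]) / gtm.tau;
  d[TS_HT] = (gth.inf - s[TS_HT]) / gth.tau;
  double eca = eca_nernst(s[TS_CA]);
  double gT = p.g_T * s[TS_MT] * s[TS_MT] * s[TS_HT];
  double iT = gT * (v - eca);
  double gh_tot = 0.0;
  if (p.is_tc && p.g_h > 0) {
    Gate go = ih_o(v);
    double alpha = go.inf / go.tau, beta = (1.0 - go.inf) / go.tau;
    double c1 = 1.0 - s[TS_O1] - s[TS_O2];
    double r = s[TS_CA] / p.ih_cac;
    double k1ca = IH_K2 * r * r * r * r;
    double k3p = IH_K4 * (s[TS_P1] / IH_PC);
    d[TS_O1] = alpha * c1 - beta * s[TS_O1] - k3p * s[TS_O1] +
               IH_K4 * s[TS_O2];
    d[TS_P1] = k1ca * (1.0 - s[TS_P1]) - IH_K2 * s[TS_P1];
    d[TS_O2] = k3p * s[TS_O1] - IH_K4 * s[TS_O2];
    gh_tot = p.g_h * (s[TS_O1] + IH_GINC * s[TS_O2]);
  }
  double iNa = p.g_Na * s[TS_M] * s[TS_M] * s[TS_M] * s[TS_H] *
               (v - p.E_Na);
  double iK = p.g_K * std::pow(s[TS_N], 4) * (v - p.E_K);
  double iKL = p.g_KL * (v - p.E_KL);
  double ih_cur = gh_tot * (v - p.E_h);
  double iint = iNa + iK + iT + iKL + ih_cur;
  d[TS_V] = (-p.g_leak * (v - p.E_leak) - iint - I_syn) / p.Cm;
  d[TS_CA] = -CA_DRIVE * iT + (p.ca_inf - s[TS_CA]) / p.tau_ca;
  return d;
}

// [[Rcpp::export]]
List cort_deriv_cpp(NumericVector state, List params, double I_syn) {
  CortP p = cort_params(params);
  const double* s = state.begin();
  double vd = s[CS_VD], vs = s[CS_VS];
  NumericVector d(NSTATE);
  Gate g;
  g = cort_na_m(vd); d[CS_MD] = (g.inf - s[CS_MD]) / g.tau;
  g = cort_na_h(vd); d[CS_HD] = (g.inf - s[CS_HD]) / g.tau;
  g = cort_na_m(vs); d[CS_MS] = (g.inf - s[CS_MS]) / g.tau;
  g = cort_na_h(vs); d[CS_HS] = (g.inf - s[CS_HS]) / g.tau;
  g = cort_kv_n(vs); d[CS_NS] = (g.inf - s[CS_NS]) / g.tau;
  g = cort_km_n(vd); d[CS_KM] = (g.inf - s[CS_KM]) / g.tau;
  g = cort_hva_m(vd); d[CS_HVA_M] = (g.inf - s[CS_HVA_M]) / g.tau;
  g = cort_hva_h(vd); d[CS_HVA_H] = (g.inf - s[CS_HVA_H]) / g.tau;
  double aK = kca_alpha(s[CS_CA]), bK = KCA_RB;
  d[CS_KCA] = TADJ * (aK * (1.0 - s[CS_KCA]) - bK * s[CS_KCA]);
  double eca = eca_nernst(s[CS_CA]);
  double gNad = p.g_Na_d * std::pow(s[CS_MD], 3) * s[CS_HD];
  double gHVA = p.g_HVA * s[CS_HVA_M] * s[CS_HVA_M] * s[CS_HVA_H];
  double iHVA = gHVA * (vd - eca);
  double i_d =
      p.g_L * (vd - p.E_leak) + p.g_KL * (vd - p.E_KL) +
      gNad * (vd - p.E_Na) + p.g_Nap_d * nap_minf(vd) * (vd - p.E_Na) +
      iHVA + p.g_KCa * s[CS_KCA] * (vd - p.E_K) +
      p.g_Km * s[CS_KM] * (vd - p.E_K);
  double ax_dend = p.kappa_d * (vd - vs);
  d[CS_VD] = (-i_d - ax_dend - I_syn) / p.Cm_d;
  d[CS_CA] = -CA_DRIVE * iHVA + (p.ca_inf - s[CS_CA]) / p.tau_ca;
  double gNas = p.g_Na_s * std::pow(s[CS_MS], 3) * s[CS_HS];
  double gKs = p.g_K_s * s[CS_NS];
  double gNaps = p.g_Nap_s * nap_minf(vs);
  double vstar = (p.kappa_s * vd + (gNas + gNaps) * p.E_Na +
                  gKs * p.E_K) /
                 (p.kappa_s + gNas + gNaps + gKs);
  d[CS_VS] = 0.0;  // zero-capacitance compartment: algebraic, not ODE
  return List::create(
      _["derivs"] = d, _["v_s_star"] = vstar,
      _["ax_dend"] = ax_dend,
      _["ax_soma"] = p.kappa_s * (vs - vd));
}

static void default_thal_init(double* s, const ThalP& p, double v0) {
  s[TS_V] = v0;
  double vna = v0 - p.vshift;
  s[TS_M] = thal_na_m(vna).inf; s[TS_H] = thal_na_h(vna).inf;
  s[TS_N] = thal_k_n(vna).inf;
  s[TS_MT] = (p.is_tc ? tc_it_m(v0) : re_it_m(v0)).inf;
  s[TS_HT] = (p.is_tc ? tc_it_h(v0) : re_it_h(v0)).inf;
  s[TS_CA] = p.ca_inf;
  s[TS_O1] = ih_o(v0).inf; s[TS_P1] = 0.0; s[TS_O2] = 0.0;
}

static void default_cort_init(double* s, const CortP& p, double v0) {
  s[CS_VD] = v0; s[CS_VS] = v0;
  s[CS_MD] = s[CS_MS] = cort_na_m(v0).inf;
  s[CS_HD] = s[CS_HS] = cort_na_h(v0).inf;
  s[CS_NS] = cort_kv_n(v0).inf;
  s[CS_KM] = cort_km_n(v0).inf;
  s[CS_KCA] = 0.0;
  s[CS_HVA_M] = cort_hva_m(v0).inf; s[CS_HVA_H] = cort_hva_h(v0).inf;
  s[CS_CA] = p.ca_inf;
}

// [[Rcpp::export]]
List single_cell_cpp(int type, List params, double dt, double duration,
                     NumericVector stim_on, NumericVector stim_off,
                     NumericVector stim_amp, double record_dt,
                     Nullable<NumericVector> init) {
  bool cortical = type >= 2;
  Tables T;
  T.build(dt, -25.0, 12.5);
  ThalP tp; CortP cp;
  if (cortical) cp = cort_params(params); else tp = thal_params(params);
  double s[NSTATE];
  std::memset(s, 0, sizeof(s));
  if (init.isNotNull()) {
    NumericVector iv(init);
    for (int i = 0; i < iv.size() && i < NSTATE; ++i) s[i] = iv[i];
  } else if (cortical) {
    default_cort_init(s, cp, -68.0);
  } else {
    default_thal_init(s, tp, -68.0);
  }
  long nsteps = (long)std::llround(duration / dt);
  int stride = std::max(1, (int)std::lround(record_dt / dt));
  long nrec = nsteps / stride;
  NumericVector time(nrec), V(nrec), Vd(cortical ? nrec : 0);
  double eca = eca_nernst(cortical ? s[CS_CA] : s[TS_CA]);
  long irec = 0;
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double inj = 0.0;
    for (int j = 0; j < stim_on.size(); ++j) {
      if (t >= stim_on[j] && t < stim_off[j]) inj += stim_amp[j];
    }
    if (k % 40 == 0) {
      eca = eca_nernst(cortical ? s[CS_CA] : s[TS_CA]);
    }
    if (cortical) cort_step(s, cp, T, dt, 0, 0, inj, eca);
    else thal_step(s, tp, T, dt, 0, 0, inj, eca);
    if ((k + 1) % stride == 0 && irec < nrec) {
      time[irec] = t + dt;
      V[irec] = cortical ? s[CS_VS] : s[TS_V];
      if (cortical) Vd[irec] = s[CS_VD];
      ++irec;
    }
    double v = cortical ? s[CS_VS] : s[TS_V];
    if (!std::isfinite(v) || std::fabs(v) > 150.0) {
      stop("numerical blow-up at t = %.2f ms (single cell)", t);
    }
  }
  int nst = cortical ? NSTATE : 10;
  NumericVector fin(nst);
  for (int i = 0; i < nst; ++i) fin[i] = s[i];
  List out = List::create(_["time"] = time, _["V"] = V,
                          _["state"] = fin);
  if (cortical) out["V_dend"] = Vd;
  return out;
}

// ------------------------------------------------------------ network

// [[Rcpp::export]]
List run_network_cpp(IntegerVector pop_class, IntegerVector pop_size,
                     List params, List init,
                     IntegerVector src, IntegerVector tgt,
                     IntegerVector rec, NumericVector w,
                     LogicalVector depressing, LogicalVector mini,
                     NumericVector syn_const,
                     double dt, double duration_ms, double lfp_dt,
                     int seed, double mini_scale,
                     double depress_U, double depress_tau,
                     IntegerVector record_pops, int n_groups,
                     bool record_cells, IntegerVector record_v,
                     IntegerVector stim_gid, NumericVector stim_on,
                     NumericVector stim_off, NumericVector stim_amp) {
  const int npop = pop_class.size();
  int n = 0;
  std::vector<int> offset(npop);
  for (int p = 0; p < npop; ++p) { offset[p] = n; n += pop_size[p]; }

  std::vector<int> cls(n), popof(n);
  for (int p = 0; p < npop; ++p) {
    for (int i = 0; i < pop_size[p]; ++i) {
      cls[offset[p] + i] = pop_class[p];
      popof[offset[p] + i] = p;
    }
  }
  std::vector<ThalP> tps(npop); std::vector<CortP> cps(npop);
  for (int p = 0; p < npop; ++p) {
    List pl = params[p];
    if (pop_class[p] >= 2) cps[p] = cort_params(pl);
    else tps[p] = thal_params(pl);
  }

  SynConst SC;
  SC.init(syn_const);
  Tables T;
  T.build(dt, SC.nmda_vth, SC.nmda_delta);

  // state
  std::vector<double> S((size_t)n * NSTATE, 0.0);
  for (int p = 0; p < npop; ++p) {
    NumericMatrix m = init[p];
    for (int i = 0; i < pop_size[p]; ++i) {
      double* s = &S[(size_t)(offset[p] + i) * NSTATE];
      for (int k = 0; k < m.nrow(); ++k) s[k] = m(k, i);
    }
  }

  // synaptic aggregates per target cell
  std::vector<double> A_ampa(n, 0), A_nmda(n, 0), A_gabaa(n, 0);
  std::vector<double> Rgb(n, 0), Ggb(n, 0), Wgb(n, 0);
  const int ne = src.size();
  for (int e = 0; e < ne; ++e) {
    if (rec[e] == R_GABAB) Wgb[tgt[e]] += w[e];
  }
  double dec_ampa = std::exp(-SC.b[0] * dt);
  double dec_nmda = std::exp(-SC.b[1] * dt);
  double dec_gabaa = std::exp(-SC.b[2] * dt);
  double dec_R = std::exp(-SC.K2 * dt);

  // per-presynaptic-neuron shared receptor state
  std::vector<double> Ofast(n, 0), Oslow(n, 0), Dav(n, 1.0);
  std::vector<double> tlast(n, -1e30);
  std::vector<char> refr(n, 0);
  std::vector<double> last_spk(n, -1e30);

  // CSR edges by source
  std::vector<int> eptr(n + 1, 0);
  for (int e = 0; e < ne; ++e) eptr[src[e] + 1]++;
  for (int i = 0; i < n; ++i) eptr[i + 1] += eptr[i];
  std::vector<int> e_tgt(ne), e_rec(ne);
  std::vector<double> e_w(ne);
  std::vector<char> e_dep(ne);
  {
    std::vector<int> cur(eptr.begin(), eptr.end() - 1);
    for (int e = 0; e < ne; ++e) {
      int k = cur[src[e]]++;
      e_tgt[k] = tgt[e]; e_rec[k] = rec[e]; e_w[k] = w[e];
      e_dep[k] = depressing[e] ? 1 : 0;
    }
  }
  std::vector<char> has_dep(n, 0);
  for (int e = 0; e < ne; ++e) if (depressing[e]) has_dep[src[e]] = 1;

  // mini-carrying edges (cortical chemical synapses)
  struct MiniEdge { int src, tgt, rec; double w; };
  std::vector<MiniEdge> me;
  for (int e = 0; e < ne; ++e) {
    if (mini[e]) me.push_back({src[e], tgt[e], rec[e], w[e]});
  }
  double mini_lambda = me.size() / 250.0;  // bound, events per ms

  // recording layout
  std::vector<int> rec_slot(n, -1), rec_group(n, -1);
  int nrp = record_pops.size();
  std::vector<int> gsize(nrp);
  for (int r = 0; r < nrp; ++r) {
    int p = record_pops[r];
    int gs = pop_size[p] / n_groups;
    gsize[r] = gs;
    for (int i = 0; i < gs * n_groups; ++i) {
      rec_slot[offset[p] + i] = r;
      rec_group[offset[p] + i] = i / gs;
    }
  }
  long nsteps = (long)std::llround(duration_ms / dt);
  int stride = std::max(1, (int)std::lround(lfp_dt / dt));
  long nsamp = nsteps / stride;
  std::vector<NumericMatrix> lfp;
  std::vector<NumericMatrix> cellbuf;
  for (int r = 0; r < nrp; ++r) {
    lfp.push_back(NumericMatrix(nsamp, n_groups));
    if (record_cells) {
      cellbuf.push_back(NumericMatrix(nsamp, pop_size[record_pops[r]]));
    }
  }
  std::vector<std::vector<double>> gacc(nrp,
      std::vector<double>(n_groups, 0.0));
  std::vector<double> cacc(record_cells ? n : 0, 0.0);
  NumericMatrix vbuf(record_v.size() ? nsamp : 0, record_v.size());

  std::vector<int> spk_id; std::vector<double> spk_t;
  spk_id.reserve(1 << 16); spk_t.reserve(1 << 16);

  std::mt19937_64 rng(0x5eed0000u + (unsigned)seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  double next_mini = 1e300;
  if (!me.empty()) {
    next_mini = -std::log(U01(rng)) / mini_lambda;
  }

  std::vector<double> inj(n, 0.0);
  std::vector<double> eca(n);
  for (int c = 0; c < n; ++c) {
    double* s = &S[(size_t)c * NSTATE];
    eca[c] = eca_nernst(cls[c] >= 2 ? s[CS_CA] : s[TS_CA]);
  }
  const int nstim = stim_gid.size();

  long isamp = 0;
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;

    // miniature PSPs in (t, t+dt]
    while (next_mini <= t + dt) {
      const MiniEdge& m0 = me[(size_t)(U01(rng) * me.size()) % me.size()];
      double dtl = next_mini - tlast[m0.src];
      double ratio = 2.0 / (1.0 + std::exp(-dtl / 400.0)) - 1.0;
      if (ratio > 0 && U01(rng) < ratio) {
        double add = m0.w * mini_scale * SC.dO_gain[m0.rec] *
                     (m0.rec == R_NMDA ? SC.Oinf[1] : SC.Oinf[m0.rec]);
        if (m0.rec == R_AMPA) A_ampa[m0.tgt] += add;
        else if (m0.rec == R_NMDA) A_nmda[m0.tgt] += add;
        else if (m0.rec == R_GABAA) A_gabaa[m0.tgt] += add;
      }
      next_mini += -std::log(U01(rng)) / mini_lambda;
    }

    // stims
    if (nstim) {
      std::fill(inj.begin(), inj.end(), 0.0);
      for (int j = 0; j < nstim; ++j) {
        if (t >= stim_on[j] && t < stim_off[j]) {
          inj[stim_gid[j]] += stim_amp[j];
        }
      }
    }

    bool refresh_eca = (k % 40 == 0);

    // integrate cells population by population
    for (int p = 0; p < npop; ++p) {
      bool cortical = pop_class[p] >= 2;
      const ThalP& tp = tps[p];
      const CortP& cp = cps[p];
      bool is_tc_pop = pop_class[p] == 0;
      for (int i = 0; i < pop_size[p]; ++i) {
        int c = offset[p] + i;
        double* s = &S[(size_t)c * NSTATE];
        if (refresh_eca) {
          eca[c] = eca_nernst(cortical ? s[CS_CA] : s[TS_CA]);
        }
        double v_post = cortical ? s[CS_VD] : s[TS_V];
        double e_ga = is_tc_pop ? -80.0 : -70.0;
        double gA = A_ampa[c];
        double gN = A_nmda[c] * T.gate_nmda(v_post);
        double gG = A_gabaa[c];
        double synG = gA + gN + gG;
        double synGE = gG * e_ga;
        if (Wgb[c] > 0) {
          double g4 = Ggb[c] * Ggb[c] * Ggb[c] * Ggb[c];
          double ggb = Wgb[c] * g4 / (g4 + SC.Kd);
          synG += ggb; synGE += ggb * (-95.0);
        }
        if (rec_slot[c] >= 0) {
          double isyn_d = synG * v_post - synGE;  // outward positive
          gacc[rec_slot[c]][rec_group[c]] += isyn_d;
          if (record_cells) cacc[c] += isyn_d;
        }
        if (cortical) {
          cort_step(s, cp, T, dt, synG, synGE, nstim ? inj[c] : 0.0,
                    eca[c]);
        } else {
          thal_step(s, tp, T, dt, synG, synGE, nstim ? inj[c] : 0.0,
                    eca[c]);
        }
        // aggregate conductance decay
        A_ampa[c] *= dec_ampa; A_nmda[c] *= dec_nmda;
        A_gabaa[c] *= dec_gabaa;
        if (Wgb[c] > 0) {
          Ggb[c] += dt * (SC.K3 * Rgb[c] - SC.K4 * Ggb[c]);
          Rgb[c] *= dec_R;
        }
        // spike detection on the (new) somatic / sole voltage
        double vnow = cortical ? s[CS_VS] : s[TS_V];
        if (!refr[c]) {
          if (vnow >= -20.0) {
            refr[c] = 1;
            double ts = t + dt;
            if (ts - last_spk[c] >= 2.0) {
              last_spk[c] = ts;
              spk_id.push_back(c); spk_t.push_back(ts);
              // presynaptic bookkeeping + event-driven increments
              double dtl = ts - tlast[c];
              int fast = (cls[c] == 1 || cls[c] == 3) ? 2 : 0;
              double Of = Ofast[c] * std::exp(-SC.b[fast] * dtl);
              double dOf = (SC.Oinf[fast] - Of) * SC.dO_gain[fast];
              Ofast[c] = Of + dOf;
              double dOs = 0.0;
              if (cls[c] == 2) {           // PY: NMDA slow slot
                double Os = Oslow[c] * std::exp(-SC.b[1] * dtl);
                dOs = (SC.Oinf[1] - Os) * SC.dO_gain[1];
                Oslow[c] = Os + dOs;
              } else if (cls[c] == 1) {    // RE: GABA-B receptor slot
                double Rr = Oslow[c] * std::exp(-SC.K2 * dtl);
                dOs = (SC.Rinf - Rr) * SC.dR_gain;
                Oslow[c] = Rr + dOs;
              }
              double Duse = 1.0;
              if (has_dep[c]) {
                Duse = 1.0 - (1.0 - Dav[c] * (1.0 - depress_U)) *
                       std::exp(-dtl / depress_tau);
                Dav[c] = Duse;
              }
              tlast[c] = ts;
              for (int e = eptr[c]; e < eptr[c + 1]; ++e) {
                double wD = e_w[e] * (e_dep[e] ? Duse : 1.0);
                switch (e_rec[e]) {
                  case R_AMPA:  A_ampa[e_tgt[e]] += wD * dOf; break;
                  case R_NMDA:  A_nmda[e_tgt[e]] += wD * dOs; break;
                  case R_GABAA: A_gabaa[e_tgt[e]] += wD * dOf; break;
                  default:
                    if (Wgb[e_tgt[e]] > 0) {
                      Rgb[e_tgt[e]] += (e_w[e] / Wgb[e_tgt[e]]) * dOs;
                    }
                }
              }
            }
          }
        } else if (vnow < -20.0) {
          refr[c] = 0;
        }
      }
    }

    // recording
    if ((k + 1) % stride == 0 && isamp < nsamp) {
      for (int r = 0; r < nrp; ++r) {
        for (int g = 0; g < n_groups; ++g) {
          lfp[r](isamp, g) = gacc[r][g] / (stride * gsize[r]);
          gacc[r][g] = 0.0;
        }
        if (record_cells) {
          int p = record_pops[r];
          for (int i = 0; i < pop_size[p]; ++i) {
            int c = offset[p] + i;
            cellbuf[r](isamp, i) = cacc[c] / stride;
            cacc[c] = 0.0;
          }
        }
      }
      for (int j = 0; j < record_v.size(); ++j) {
        int c = record_v[j];
        const double* s = &S[(size_t)c * NSTATE];
        vbuf(isamp, j) = cls[c] >= 2 ? s[CS_VS] : s[TS_V];
      }
      ++isamp;
    }

    // stability audit
    if (k % 400 == 0) {
      for (int c = 0; c < n; ++c) {
        double v = cls[c] >= 2 ? S[(size_t)c * NSTATE + CS_VS]
                               : S[(size_t)c * NSTATE + TS_V];
        if (!std::isfinite(v) || std::fabs(v) > 150.0) {
          stop("numerical blow-up: cell %d (population %d) at "
               "t = %.2f ms", c, popof[c], t);
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }

  List lfp_out(nrp), cell_out(record_cells ? nrp : 0);
  for (int r = 0; r < nrp; ++r) {
    lfp_out[r] = lfp[r];
    if (record_cells) cell_out[r] = cellbuf[r];
  }
  List out = List::create(
      _["spike_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["lfp"] = lfp_out, _["v_traces"] = vbuf);
  if (record_cells) out["cell_currents"] = cell_out;
  return out;
}
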