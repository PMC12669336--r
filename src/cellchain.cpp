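// 0D cellular chain of the neuro-glial-vascular unit.
//
// Fast block (dt_fast, default 0.01 ms): two presynaptic terminals (Glu,
// GABA) with Hodgkin-Huxley spiking (RK4), N-type gate (exact exponential
// update), fast/slow bouton calcium (explicit Euler), stochastic vesicle
// sensors (exact SSA on the 7-state chain), Tsodyks-Markram pools with
// impulsive release + refractory lockout, cleft transmitter.
//
// Slow block (dt_slow = 10*dt_fast): stochastic astrocyte G-ChI
// (Euler-Maruyama on h_a), gliotransmitter gates/pools, postsynaptic
// potential, NO pathway + cGMP, SMC/EC exchange, Hai-Murphy cross-bridges
// and the Kelvin-Voigt wall radius.
//
// Units: ms, mV, uM (transmitters mM), um, Pa. Randomness comes from R's
// RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double P(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm)) stop("missing parameter: %s", nm);
  return v[nm];
}

namespace {

struct HH { double V, n, m, h; };

inline double ratio_exp(double a, double k) { // a/(exp(a/k)-1), limit k
  if (std::fabs(a) < 1e-7) return k - a / 2;
  return a / (std::exp(a / k) - 1.0);
}

struct HHp { double C, gNa, gK, gL, VNa, VK, VL; };

void hh_rhs(const HH& s, double Iapp, const HHp& p, HH& d) {
  double an = 0.01 * ratio_exp(-s.V - 60, 10);
  double bn = 0.125 * std::exp((-s.V - 70) / 80);
  double am = 0.1 * ratio_exp(-s.V - 45, 10);
  double bm = 4 * std::exp((-s.V - 70) / 18);
  double ah = 0.07 * std::exp((-s.V - 70) / 20);
  double bh = 1.0 / (std::exp((-s.V - 40) / 10) + 1);
  double INa = p.gNa * s.m * s.m * s.m * s.h * (s.V - p.VNa);
  double IK = p.gK * std::pow(s.n, 4) * (s.V - p.VK);
  double IL = p.gL * (s.V - p.VL);
  d.V = (Iapp - IK - INa - IL) / p.C;
  d.n = an * (1 - s.n) - bn * s.n;
  d.m = am * (1 - s.m) - bm * s.m;
  d.h = ah * (1 - s.h) - bh * s.h;
}

void hh_rk4(HH& s, double Iapp, const HHp& p, double dt) {
  HH k1, k2, k3, k4, t;
  hh_rhs(s, Iapp, p, k1);
  t = {s.V + dt / 2 * k1.V, s.n + dt / 2 * k1.n, s.m + dt / 2 * k1.m,
       s.h + dt / 2 * k1.h};
  hh_rhs(t, Iapp, p, k2);
  t = {s.V + dt / 2 * k2.V, s.n + dt / 2 * k2.n, s.m + dt / 2 * k2.m,
       s.h + dt / 2 * k2.h};
  hh_rhs(t, Iapp, p, k3);
  t = {s.V + dt * k3.V, s.n + dt * k3.n, s.m + dt * k3.m, s.h + dt * k3.h};
  hh_rhs(t, Iapp, p, k4);
  s.V += dt / 6 * (k1.V + 2 * k2.V + 2 * k3.V + k4.V);
  s.n += dt / 6 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
  s.m += dt / 6 * (k1.m + 2 * k2.m + 2 * k3.m + k4.m);
  s.h += dt / 6 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
}

inline double hillf(double x, double K, double n) {
  if (x <= 0) return 0.0;
  double xn = std::pow(x, n);
  return xn / (xn + std::pow(K, n));
}

// One presynaptic terminal (shared structure for Glu and GABA)
struct Terminal {
  HH hh;
  double mCa, c_fast, c_slow, c_ER, p_ip3, q;
  int sensor[2];        // 1..7
  double R, E, t_last;
  double g;             // cleft transmitter (mM)
};

struct SynP {
  HHp hhp;
  double Iapp;
  double rho_Ca, g_Ca, V_mCa, k_mCa, tau_mCa, c_ext, c_rest, VCa;
  double A_btn, V_btn, conv;     // conv: fA/um^2 -> uM/ms (incl. A/(zFV))
  double v_leak, K_PM, v_PM;
  double c1, v1, v2, v3, k3, d1, d2, d3, d5, a2, p0, v_g, k_g, tau_p;
  double alpha_s, beta_s, gamma_s, delta_s;
  double a1_sp, a2_sp, a3_sp;
  double tau_rec, tau_inact, lockout;
  double n_v, g_v, g_c;
};

void terminal_fast_step(Terminal& T, const SynP& sp, double g_a, double t,
                        double dt, bool stochastic) {
  // order: (1) N-type gate from current V, (2) calcium fluxes from current
  // state, (3) sensors/release, (4) pools + cleft, (5) HH update.
  double m_inf = 1.0 / (1.0 + std::exp((sp.V_mCa - T.hh.V) / sp.k_mCa));
  T.mCa = m_inf + (T.mCa - m_inf) * std::exp(-dt / sp.tau_mCa);
  double ICa = sp.rho_Ca * T.mCa * T.mCa * sp.g_Ca * (T.hh.V - sp.VCa);
  double ci = T.c_fast + T.c_slow;
  double Ipm = sp.v_PM * ci * ci / (ci * ci + sp.K_PM * sp.K_PM);
  double dcf = -ICa * sp.conv + sp.v_leak * (sp.c_ext - ci) - Ipm * sp.conv;
  double mi = T.p_ip3 / (T.p_ip3 + sp.d1);
  double ni = ci / (ci + sp.d5);
  double gate = mi * ni * T.q;
  double Jchan = sp.c1 * sp.v1 * gate * gate * gate * (ci - T.c_ER);
  double Jpump = sp.v3 * ci * ci / (sp.k3 * sp.k3 + ci * ci);
  double Jleak = sp.c1 * sp.v2 * (ci - T.c_ER);
  double dcs = -Jchan - Jpump - Jleak;
  double ga03 = (g_a > 0) ? std::pow(g_a, 0.3) : 0.0;
  double dp = sp.v_g * ga03 / (std::pow(sp.k_g, 0.3) + ga03) -
    sp.tau_p * (T.p_ip3 - sp.p0);
  double aq = sp.a2 * sp.d2 * (T.p_ip3 + sp.d1) / (T.p_ip3 + sp.d3);
  double bq = sp.a2 * ci;
  double dq = aq * (1 - T.q) - bq * T.q;

  // sensors: exact SSA per vesicle over [0, dt] at frozen ci
  int n_rel = 0;
  if (stochastic) {
    double a = sp.alpha_s * ci, b = sp.beta_s;
    for (int v = 0; v < 2; ++v) {
      double tt = 0.0; int s = T.sensor[v];
      for (;;) {
        double fwd = 0, bwd = 0;
        if (s <= 5) fwd = (6 - s) * a;           // s=1..5: binding
        if (s == 6) fwd = sp.gamma_s;            // isomerisation
        if (s >= 2 && s <= 6) bwd = (s - 1) * b; // unbinding
        if (s == 7) bwd = sp.delta_s;
        double tot = fwd + bwd;
        if (tot <= 0) break;
        tt += R::exp_rand() / tot;
        if (tt > dt) break;
        s += (R::unif_rand() * tot < fwd) ? 1 : -1;
        if (s == 7 && (t - T.t_last) >= sp.lockout) {
          ++n_rel; s = 1;
        }
      }
      T.sensor[v] = s;
    }
    // spontaneous Poisson release (one vesicle per event)
    double lam = sp.a3_sp / (1.0 + std::exp((sp.a1_sp - ci) / sp.a2_sp));
    if (R::unif_rand() < lam * dt && (t - T.t_last) >= sp.lockout) ++n_rel;
  }
  if (n_rel > 0) {
    double fr = 0.5 * std::min(n_rel, 2);
    double rel = fr * T.R;
    T.R -= rel; T.E += rel; T.t_last = t;
  }
  double I = 1 - T.R - T.E;
  T.R += dt * I / sp.tau_rec;
  T.E *= std::exp(-dt / sp.tau_inact);
  T.g += dt * (sp.n_v * sp.g_v * T.E - sp.g_c * T.g);

  T.c_fast += dt * dcf;
  T.c_slow += dt * dcs;
  T.c_ER += dt * (-dcs / sp.c1);
  T.p_ip3 += dt * dp;
  T.q += dt * dq;
  if (T.q < 0) T.q = 0; if (T.q > 1) T.q = 1;
  if (T.c_fast < 0) T.c_fast = 0;
  hh_rk4(T.hh, sp.Iapp, sp.hhp, dt);
}

} // namespace

// [[Rcpp::export(name = ".cell_chain_run")]]
List cell_chain_run(NumericVector ps, NumericVector pn, List control) {
  double t_end = as<double>(control["t_end_ms"]);
  double dt = as<double>(control["dt_fast_ms"]);
  int slow_every = as<int>(control["slow_every"]);
  double sample_ms = as<double>(control["sample_ms"]);
  bool stochastic = as<bool>(control["stochastic"]);
  double N_IP3 = as<double>(control["N_IP3"]);
  double dt_s = dt * slow_every;

  // --- synapse parameters -------------------------------------------------
  const double F = 96485.332, Rgas = 8.314462, TK = 300.0;
  SynP sg; // Glu terminal
  sg.hhp = {P(ps, "C_m"), P(ps, "g_Na"), P(ps, "g_K"), P(ps, "g_L"),
            P(ps, "V_Na"), P(ps, "V_K"), P(ps, "V_L")};
  sg.Iapp = P(ps, "I_app_glu");
  sg.rho_Ca = P(ps, "rho_Ca"); sg.g_Ca = P(ps, "g_Ca");
  sg.V_mCa = P(ps, "V_mCa"); sg.k_mCa = P(ps, "k_mCa");
  sg.tau_mCa = P(ps, "tau_mCa"); sg.c_ext = P(ps, "c_ext");
  sg.c_rest = P(ps, "c_i_rest");
  sg.VCa = 1e3 * Rgas * TK / (2 * F) * std::log(sg.c_ext / sg.c_rest);
  sg.A_btn = P(ps, "A_btn"); sg.V_btn = P(ps, "V_btn");
  sg.conv = sg.A_btn / (2 * F * sg.V_btn) * 1e3;
  sg.v_leak = P(ps, "v_leak"); sg.K_PM = P(ps, "K_PM_Ca");
  sg.v_PM = P(ps, "v_PM_Ca");
  sg.c1 = P(ps, "c1_er"); sg.v1 = P(ps, "v1"); sg.v2 = P(ps, "v2");
  sg.v3 = P(ps, "v3"); sg.k3 = P(ps, "k3");
  sg.d1 = P(ps, "d1"); sg.d2 = P(ps, "d2"); sg.d3 = P(ps, "d3");
  sg.d5 = P(ps, "d5"); sg.a2 = P(ps, "a2"); sg.p0 = P(ps, "p0");
  sg.v_g = P(ps, "v_g"); sg.k_g = P(ps, "k_g"); sg.tau_p = P(ps, "tau_p");
  sg.alpha_s = P(ps, "alpha_s"); sg.beta_s = P(ps, "beta_s");
  sg.gamma_s = P(ps, "gamma_s"); sg.delta_s = P(ps, "delta_s");
  sg.a1_sp = P(ps, "a1_sp"); sg.a2_sp = P(ps, "a2_sp");
  sg.a3_sp = P(ps, "a3_sp");
  sg.tau_rec = P(ps, "tau_rec"); sg.tau_inact = P(ps, "tau_inact_glu");
  sg.lockout = P(ps, "lockout_glu");
  sg.n_v = P(ps, "n_v"); sg.g_v = P(ps, "g_v_glu"); sg.g_c = P(ps, "g_c");
  SynP sb = sg; // GABA terminal
  sb.Iapp = P(ps, "I_app_gaba");
  sb.tau_inact = P(ps, "tau_inact_gaba");
  sb.lockout = P(ps, "lockout_gaba");
  sb.g_v = P(ps, "g_v_gaba");

  // astrocyte
  double r_Ca = P(ps, "r_Ca"), v_ER = P(ps, "v_ER_a"),
    K_ER = P(ps, "K_ER_a"), r_L = P(ps, "r_L"), c0a = P(ps, "c0_a"),
    c1a = P(ps, "c1_a"), v_beta = P(ps, "v_beta"), K_R = P(ps, "K_R"),
    K_pa = P(ps, "K_p_a"), K_pi = P(ps, "K_pi"),
    v_delta = P(ps, "v_delta"), k_delta = P(ps, "k_delta"),
    K_PLCd = P(ps, "K_PLCdelta"), v_3K = P(ps, "v_3K"),
    K_D = P(ps, "K_D"), K_3 = P(ps, "K_3"), r_5P = P(ps, "r_5P");
  double km_g[3] = {P(ps, "k1_minus"), P(ps, "k2_minus"), P(ps, "k3_minus")};
  double Kd_g[3] = {P(ps, "Kd1_a"), P(ps, "Kd2_a"), P(ps, "Kd3_a")};
  double ca_th = P(ps, "c_a_thresh"), tau_rec_a = P(ps, "tau_rec_a"),
    tau_inact_a = P(ps, "tau_inact_a"), k_rel_a = P(ps, "k_rel_a");
  double n_av = P(ps, "n_av"), g_av = P(ps, "g_av_glu"),
    g_av_b = P(ps, "g_av_gaba"), g_ac = P(ps, "g_ac");

  // NVC / NO
  double P_Ca = P(pn, "P_Ca"), G_vc = P(pn, "G_v"), P_IP3 = P(pn, "P_IP3"),
    buf = P(pn, "buf_free"),
    F_i = P(pn, "F_i"), K_ri = P(pn, "K_ri"), Jleak_i = P(pn, "J_leak_i"),
    k_ex_i = P(pn, "k_ex_i"), B_i = P(pn, "B_i"), c_bi = P(pn, "c_bi"),
    k_voc = P(pn, "k_voc"), v_voc0 = P(pn, "v_voc0"),
    F_j = P(pn, "F_j"), K_rj = P(pn, "K_rj"), k_ex_j = P(pn, "k_ex_j"),
    J_EC = P(pn, "J_EC_IP3"), k_dip = P(pn, "k_deg_ip3"),
    tau_v = P(pn, "tau_v"), v_L_i = P(pn, "v_L_i"), v_K_i = P(pn, "v_K_i"),
    G_KIR = P(pn, "G_KIR_eff"), z1 = P(pn, "z1"), z2 = P(pn, "z2"),
    K_p = P(pn, "K_p"), G_BK = P(pn, "G_BK"), v3b = P(pn, "v3_BK"),
    v4b = P(pn, "v4_BK"), eps_bk = P(pn, "eps_bk"),
    al_bk = P(pn, "alpha_bk"), ga_bk = P(pn, "gamma_bk"),
    s_BK = P(pn, "s_BK"),
    g_cr = P(pn, "gamma_cross"), K3c = P(pn, "K3_cb"), K4c = P(pn, "K4_cb"),
    K7c = P(pn, "K7_cb"), d_i = P(pn, "delta_i"),
    kb = P(pn, "k_mlpc_b"), kc = P(pn, "k_mlpc_c"),
    Kmm = P(pn, "K_m_mlcp"), Ca_ref = P(pn, "Ca_ref_max"),
    eta = P(pn, "eta_wall"), E_pas = P(pn, "E_pas"), E_act = P(pn, "E_act"),
    R0p = P(pn, "R0_pas"), R0a = P(pn, "R0_act"), dpw = P(pn, "dp_wall"),
    VmaxNn = P(pn, "V_max_NO_n"), KmO2n = P(pn, "K_m_O2_n"),
    O2n = P(pn, "O2_n"), KmLn = P(pn, "K_m_LArg_n"), LArgn = P(pn, "LArg_n"),
    K_mA = P(pn, "K_mA"), K_mB = P(pn, "K_mB"), G_M = P(pn, "G_M"),
    PCaPM = P(pn, "PCa_PM"), Caex = P(pn, "Ca_ex_nmda"),
    Mmono = P(pn, "M_mono"), al_v = P(pn, "alpha_v_nmda"),
    be_v = P(pn, "beta_v_nmda"), kact = P(pn, "k_act_nNOS"),
    kdeact = P(pn, "k_deact_nNOS"), nNOS_tot = P(pn, "nNOS_tot"),
    VmaxNj = P(pn, "V_max_NO_j"), KmO2j = P(pn, "K_m_O2_j"),
    O2j = P(pn, "O2_j"), KmLj = P(pn, "K_m_LArg_j"), LArgj = P(pn, "LArg_j"),
    e_base = P(pn, "e_base"), e_Ca = P(pn, "e_Ca"), K_eCa = P(pn, "K_eCa"),
    g_wss = P(pn, "g_wss"), K_wss = P(pn, "K_wss"), Q_wss = P(pn, "Q_wss"),
    mu_wss = P(pn, "mu_wss"),
    D_NO = P(pn, "D_NO"), dx_na = P(pn, "dx_na"), dx_as = P(pn, "dx_as"),
    dx_se = P(pn, "dx_se"), ln_n = P(pn, "lam_NO_n"),
    ln_a = P(pn, "lam_NO_a"), ln_s = P(pn, "lam_NO_s"),
    ln_e = P(pn, "lam_NO_e"), VcG = P(pn, "V_cGMP"),
    K_sGC = P(pn, "K_NO_sGC"), k_pde = P(pn, "k_pde"),
    C_post = P(pn, "C_post"), gLp = P(pn, "g_L_post"),
    VLp = P(pn, "V_L_post"), g_ampa = P(pn, "g_ampa"),
    K_ampa = P(pn, "K_ampa"), V_ampa = P(pn, "V_ampa"),
    g_nmda = P(pn, "g_nmda"), V_nmda = P(pn, "V_nmda"),
    g_gabaa = P(pn, "g_gabaa"), K_gabaa = P(pn, "K_gabaa"),
    V_gabaa = P(pn, "V_gabaa"), g_gabab = P(pn, "g_gabab"),
    K_gabab = P(pn, "K_gabab"), V_gabab = P(pn, "V_gabab");

  double tau_na = dx_na * dx_na / (2 * D_NO);
  double tau_as = dx_as * dx_as / (2 * D_NO);
  double tau_se = dx_se * dx_se / (2 * D_NO);
  double v_kir = z1 * K_p - z2;

  // cross-bridge normalisation: steady attached fraction at Ca_ref, cGMP 0
  double Fr_norm;
  {
    double K1 = g_cr * Ca_ref * Ca_ref * Ca_ref;
    double K2 = d_i * kb;
    // steady state by long relaxation (small 4-state system)
    double M = 1, Mp = 0, AMp = 0, AM = 0;
    for (int it = 0; it < 2000000; ++it) {
      double dMp = K4c * AMp + K1 * M - (K2 + K3c) * Mp;
      double dAMp = K3c * Mp + K1 * AM - (K4c + K2) * AMp;
      double dAM = K2 * AMp - (K7c + K1) * AM;
      double h = 1.0;
      Mp += h * dMp; AMp += h * dAMp; AM += h * dAM;
      M = 1 - Mp - AMp - AM;
      if (std::fabs(dMp) + std::fabs(dAMp) + std::fabs(dAM) < 1e-14) break;
    }
    Fr_norm = AMp + AM;
    if (Fr_norm <= 0) Fr_norm = 1.0;
  }

  // --- initial state ------------------------------------------------------
  auto init_terminal = [&](Terminal& T, const SynP& sp) {
    T.hh.V = -70;
    double an = 0.01 * ratio_exp(70 - 60, 10); // placeholder, replaced below
    (void)an;
    // gates at steady state of V=-70
    {
      double a = 0.01 * ratio_exp(-(-70.0) - 60, 10),
        b = 0.125 * std::exp(0.0);
      T.hh.n = a / (a + b);
      a = 0.1 * ratio_exp(-(-70.0) - 45, 10); b = 4;
      T.hh.m = a / (a + b);
      a = 0.07; b = 1.0 / (std::exp(3.0) + 1);
      T.hh.h = a / (a + b);
    }
    T.mCa = 1.0 / (1.0 + std::exp((sp.V_mCa + 70) / sp.k_mCa));
    T.c_fast = sp.c_rest / 2; T.c_slow = sp.c_rest / 2;
    T.c_ER = P(ps, "c_ER0");
    T.p_ip3 = sp.p0;
    double aq = sp.a2 * sp.d2 * (sp.p0 + sp.d1) / (sp.p0 + sp.d3);
    double bq = sp.a2 * sp.c_rest;
    T.q = aq / (aq + bq);
    T.sensor[0] = T.sensor[1] = 1;
    T.R = 1; T.E = 0; T.t_last = -1e9; T.g = 0;
  };
  Terminal Tg, Tb;
  init_terminal(Tg, sg); init_terminal(Tb, sb);
  double c_a = 0.1, p_a = 0.16, h_a = 0.8;
  double O[3]; for (int j = 0; j < 3; ++j)
    O[j] = (km_g[j] / Kd_g[j]) * c_a / ((km_g[j] / Kd_g[j]) * c_a + km_g[j]);
  double R_a = 1, E_a = 0, g_a = 0, g_a_b = 0;
  double V_post = -70;
  double nNOS = 0, NOn = 0, NOa = 0, NOs = 0, NOe = 0, cGMP = 0;
  double Ca_i = 0.2, Ca_j = 0.3, IP3_i = 0.5, IP3_j = 1.0,
    v_i = -45, v_j = -50;
  double cbM = 1, cbMp = 0, cbAMp = 0, cbAM = 0;
  {
    // start cross-bridges at steady state for the initial Ca_i
    double K1 = g_cr * Ca_i * Ca_i * Ca_i, K2 = d_i * kb;
    for (int it = 0; it < 200000; ++it) {
      double dMp = K4c * cbAMp + K1 * cbM - (K2 + K3c) * cbMp;
      double dAMp = K3c * cbMp + K1 * cbAM - (K4c + K2) * cbAMp;
      double dAM = K2 * cbAMp - (K7c + K1) * cbAM;
      cbMp += dMp; cbAMp += dAMp; cbAM += dAM;
      cbM = 1 - cbMp - cbAMp - cbAM;
      if (std::fabs(dMp) + std::fabs(dAMp) + std::fabs(dAM) < 1e-14) break;
    }
  }
  double R_um = P(pn, "R_init");

  // --- output -------------------------------------------------------------
  CharacterVector cols = CharacterVector::create(
    "t_ms", "V_glu", "V_gaba", "ci_glu", "cer_glu", "p_glu", "q_glu",
    "R_glu", "E_glu", "g_glu", "ci_gaba", "cer_gaba", "g_gaba",
    "c_a", "p_a", "h_a", "O1", "O2", "O3", "R_a", "E_a", "I_a", "g_a",
    "V_post", "nNOS", "NO_n", "NO_a", "NO_s", "NO_e", "cGMP",
    "Ca_i", "Ca_j", "IP3_i", "IP3_j", "v_i", "v_j",
    "M", "Mp", "AMp", "AM", "F_r", "R_um");
  int ncol = cols.size();
  long nsteps = (long)std::ceil(t_end / dt - 1e-9);
  int sample_every = std::max(1, (int)std::round(sample_ms / dt));
  long nrow = nsteps / sample_every + 1;
  NumericMatrix out(nrow, ncol);
  long orow = 0;
  auto record = [&](double t) {
    if (orow >= nrow) return;
    double Fr = (cbAMp + cbAM) / Fr_norm;
    double vals[42] = {t, Tg.hh.V, Tb.hh.V, Tg.c_fast + Tg.c_slow, Tg.c_ER,
      Tg.p_ip3, Tg.q, Tg.R, Tg.E, Tg.g, Tb.c_fast + Tb.c_slow, Tb.c_ER,
      Tb.g, c_a, p_a, h_a, O[0], O[1], O[2], R_a, E_a, 1 - R_a - E_a, g_a,
      V_post, nNOS, NOn, NOa, NOs, NOe, cGMP, Ca_i, Ca_j, IP3_i, IP3_j,
      v_i, v_j, cbM, cbMp, cbAMp, cbAM, Fr, R_um};
    for (int c = 0; c < ncol; ++c) out(orow, c) = vals[c];
    ++orow;
  };
  record(0.0);

  double t = 0;
  for (long step = 0; step < nsteps; ++step) {
    terminal_fast_step(Tg, sg, g_a, t, dt, stochastic);
    terminal_fast_step(Tb, sb, g_a, t, dt, stochastic);

    if ((step + 1) % slow_every == 0) {
      // ---- astrocyte ----
      double mi = hillf(p_a, sg.d1, 1), ni = hillf(c_a, sg.d5, 1);
      double drive = c0a - (1 + c1a) * c_a;
      double dca = r_Ca * std::pow(mi * ni * h_a, 3) * drive -
        v_ER * hillf(c_a, K_ER, 2) + r_L * drive;
      double g_uM = Tg.g * 1e3;
      double Kr_eff = K_R * (1 + K_pa / K_R * hillf(c_a, K_pi, 1));
      double dpa = v_beta * hillf(g_uM, Kr_eff, 0.9) +
        v_delta / (1 + p_a / k_delta) * hillf(c_a, K_PLCd, 2) -
        v_3K * hillf(c_a, K_D, 4) * hillf(p_a, K_3, 1) - r_5P * p_a;
      double ah = sg.a2 * sg.d2 * (p_a + sg.d1) / (p_a + sg.d3);
      double bh = sg.a2 * c_a;
      double dha = ah * (1 - h_a) - bh * h_a;
      double noise = 0.0;
      if (stochastic && N_IP3 > 0 && R_finite(N_IP3)) {
        double var = (ah * (1 - h_a) + bh * h_a) / N_IP3;
        if (var > 0) noise = std::sqrt(var * dt_s) * R::norm_rand();
      }
      c_a = std::max(c_a + dt_s * dca, 0.0);
      p_a = std::max(p_a + dt_s * dpa, 0.0);
      h_a = h_a + dt_s * dha + noise;
      if (h_a < 0) h_a = 0; if (h_a > 1) h_a = 1;
      // gliotransmitter gates (exact exponential update)
      double fra = 1.0;
      for (int j = 0; j < 3; ++j) {
        double kp = km_g[j] / Kd_g[j];
        double oi = kp * c_a / (kp * c_a + km_g[j]);
        double tg = 1.0 / (kp * c_a + km_g[j]);
        O[j] = oi + (O[j] - oi) * std::exp(-dt_s / tg);
        fra *= O[j];
      }
      double th = (c_a > ca_th) ? 1.0 : 0.0;
      double Ia = 1 - R_a - E_a;
      double dRa = Ia / tau_rec_a - th * k_rel_a * fra * R_a;
      double dEa = -E_a / tau_inact_a + th * k_rel_a * fra * R_a;
      R_a += dt_s * dRa; E_a += dt_s * dEa;
      g_a += dt_s * (n_av * g_av * E_a - g_ac * g_a);
      g_a_b += dt_s * (n_av * g_av_b * E_a - g_ac * g_a_b);

      // ---- postsynaptic potential ----
      double sA = Tg.g / (K_ampa + Tg.g);
      double wA = (g_uM) / (K_mA + g_uM), wB = (g_uM) / (K_mB + g_uM);
      double sN = 0.5 * (wA + wB);
      double sGa = Tb.g / (K_gabaa + Tb.g);
      double sGb = Tb.g / (K_gabab + Tb.g);
      double dV = (-gLp * (V_post - VLp) - g_ampa * sA * (V_post - V_ampa) -
                   g_nmda * sN * (V_post - V_nmda) -
                   g_gabaa * sGa * (V_post - V_gabaa) -
                   g_gabab * sGb * (V_post - V_gabab)) / C_post;
      V_post += dt_s * dV;

      // ---- NO pathway ----
      double vf = 2 * (V_post * 1e-3) * F / (Rgas * TK);
      double exv = std::exp(vf);
      double ICa_nmda = 4 * V_post * G_M * PCaPM * (Caex / Mmono) /
        (1 + std::exp(al_v * (V_post + be_v))) * exv / (1 - exv);
      double ICat = ICa_nmda * (0.63 * wA + 11 * wB);
      nNOS += dt_s * (kact * std::fabs(ICat) * (nNOS_tot - nNOS) -
                      kdeact * nNOS);
      double p_n = VmaxNn * nNOS * O2n / (KmO2n + O2n) *
        LArgn / (KmLn + LArgn);
      double tau_w = 4 * mu_wss * (Q_wss * 1e-6) /
        (M_PI * std::pow(R_um * 1e-6, 3));
      double eNOS = e_base + e_Ca * hillf(Ca_j, K_eCa, 2) +
        g_wss * tau_w / (tau_w + K_wss);
      double p_e = VmaxNj * eNOS * O2j / (KmO2j + O2j) *
        LArgj / (KmLj + LArgj);
      double dNOn = p_n + (NOa - NOn) / tau_na - ln_n * NOn;
      double dNOa = (NOn - NOa) / tau_na + (NOs - NOa) / tau_as - ln_a * NOa;
      double dNOs = (NOa - NOs) / tau_as + (NOe - NOs) / tau_se - ln_s * NOs;
      double dNOe = p_e + (NOs - NOe) / tau_se - ln_e * NOe;
      NOn += dt_s * dNOn; NOa += dt_s * dNOa;
      NOs += dt_s * dNOs; NOe += dt_s * dNOe;
      cGMP += dt_s * (VcG * NOs / (K_sGC + NOs) - k_pde * cGMP);

      // ---- SMC / EC ----
      double Jkir = G_KIR * (v_i - v_kir);
      double cw = 1.0 / (eps_bk + al_bk * std::exp(ga_bk * cGMP));
      double wbk = 0.5 * (1 + std::tanh((v_i - v3b + s_BK * cw) / v4b));
      double Jca_cpl = -P_Ca * (Ca_i - Ca_j);
      double Jv_cpl = -G_vc * (v_i - v_j);
      double Jip_cpl = -P_IP3 * (IP3_i - IP3_j);
      double Jsr = B_i * c_a * c_a / (c_bi * c_bi + c_a * c_a);
      double dCai = buf * (F_i * hillf(IP3_i, K_ri, 2) + Jleak_i - Jsr -
                           k_ex_i * Ca_i + k_voc * (v_i - v_voc0)) + Jca_cpl;
      double dCaj = buf * (F_j * hillf(IP3_j, K_rj, 2) - k_ex_j * Ca_j) -
        Jca_cpl;
      double dip_i = -k_dip * IP3_i + Jip_cpl;
      double dip_j = J_EC - k_dip * IP3_j - Jip_cpl;
      double dvi = (v_L_i - v_i) / tau_v - Jkir -
        G_BK * wbk * (v_i - v_K_i) + Jv_cpl;
      double dvj = (v_L_i - v_j) / tau_v - Jv_cpl;
      Ca_i = std::max(Ca_i + dt_s * dCai, 0.0);
      Ca_j = std::max(Ca_j + dt_s * dCaj, 0.0);
      IP3_i = std::max(IP3_i + dt_s * dip_i, 0.0);
      IP3_j = std::max(IP3_j + dt_s * dip_j, 0.0);
      v_i += dt_s * dvi; v_j += dt_s * dvj;

      // ---- cross-bridges + wall ----
      double K1 = g_cr * Ca_i * Ca_i * Ca_i;
      double Rc = cGMP * cGMP / (Kmm * Kmm + cGMP * cGMP);
      double K2 = d_i * (kb + kc * Rc);
      double dMp = K4c * cbAMp + K1 * cbM - (K2 + K3c) * cbMp;
      double dAMp = K3c * cbMp + K1 * cbAM - (K4c + K2) * cbAMp;
      double dAM = K2 * cbAMp - (K7c + K1) * cbAM;
      cbMp += dt_s * dMp; cbAMp += dt_s * dAMp; cbAM += dt_s * dAM;
      cbM = 1 - cbMp - cbAMp - cbAM;
      double Fr = (cbAMp + cbAM) / Fr_norm;
      double Ew = E_pas + Fr * (E_act - E_pas);
      double R0w = R0p + Fr * (R0a - R0p);
      R_um += dt_s * (R0p / eta) * (10 * dpw - Ew * (R_um - R0w) / R0w) *
        1e-3;
    }
    t += dt;
    if ((step + 1) % sample_every == 0) record(t);
  }
  return List::create(_["trace"] = out, _["cols"] = cols,
                      _["Fr_norm"] = Fr_norm, _["dt_fast"] = dt,
                      _["dt_slow"] = dt_s);
}

// Frozen-drive wall runner: Hai-Murphy cross-bridges + Kelvin-Voigt wall
// driven by prescribed periodic SMC calcium and cGMP traces. Used by the
// sensitivity module so that hundreds of parameter draws stay cheap.
// [[Rcpp::export(name = ".wall_runner")]]
List wall_runner(NumericVector pn, List control) {
  double t_end = as<double>(control["t_end_ms"]);
  double dt = as<double>(control["dt_ms"]);
  double sample_ms = as<double>(control["sample_ms"]);
  NumericVector ca_drive = control["ca_drive"];   // sampled at drive_dt
  NumericVector cg_drive = control["cg_drive"];
  double drive_dt = as<double>(control["drive_dt_ms"]);
  double dpw = as<double>(control["dp_wall"]);
  double E_act = as<double>(control["E_act"]);
  double E_pas = as<double>(control["E_pas"]);

  double g_cr = P(pn, "gamma_cross"), K3c = P(pn, "K3_cb"),
    K4c = P(pn, "K4_cb"), K7c = P(pn, "K7_cb"), d_i = P(pn, "delta_i"),
    kb = P(pn, "k_mlpc_b"), kc = P(pn, "k_mlpc_c"), Kmm = P(pn, "K_m_mlcp"),
    Ca_ref = P(pn, "Ca_ref_max"), eta = P(pn, "eta_wall"),
    R0p = P(pn, "R0_pas"), R0a = P(pn, "R0_act");
  // normalisation as in the full chain
  double Fr_norm;
  {
    double K1 = g_cr * Ca_ref * Ca_ref * Ca_ref, K2 = d_i * kb;
    double M = 1, Mp = 0, AMp = 0, AM = 0;
    for (int it = 0; it < 2000000; ++it) {
      double dMp = K4c * AMp + K1 * M - (K2 + K3c) * Mp;
      double dAMp = K3c * Mp + K1 * AM - (K4c + K2) * AMp;
      double dAM = K2 * AMp - (K7c + K1) * AM;
      Mp += dMp; AMp += dAMp; AM += dAM; M = 1 - Mp - AMp - AM;
      if (std::fabs(dMp) + std::fabs(dAMp) + std::fabs(dAM) < 1e-14) break;
    }
    Fr_norm = AMp + AM;
  }
  long nd = ca_drive.size();
  auto drive_at = [&](const NumericVector& v, double tt) {
    double period = drive_dt * nd;
    double tm = tt - std::floor(tt / period) * period;
    double x = tm / drive_dt;
    long i0 = (long)std::floor(x) % nd;
    long i1 = (i0 + 1) % nd;
    double f = x - std::floor(x);
    return v[i0] * (1 - f) + v[i1] * f;
  };
  long nsteps = (long)std::ceil(t_end / dt - 1e-9);
  int sample_every = std::max(1, (int)std::round(sample_ms / dt));
  long nrow = nsteps / sample_every + 1;
  NumericVector Ts(nrow), Rs(nrow), Frs(nrow);
  double cbM = 1, cbMp = 0, cbAMp = 0, cbAM = 0, R_um = P(pn, "R_init");
  long orow = 0;
  double t = 0;
  Ts[orow] = 0; Rs[orow] = R_um; Frs[orow] = 0; ++orow;
  for (long step = 0; step < nsteps; ++step) {
    double Ca = drive_at(ca_drive, t);
    double cG = drive_at(cg_drive, t);
    double K1 = g_cr * Ca * Ca * Ca;
    double Rc = cG * cG / (Kmm * Kmm + cG * cG);
    double K2 = d_i * (kb + kc * Rc);
    double dMp = K4c * cbAMp + K1 * cbM - (K2 + K3c) * cbMp;
    double dAMp = K3c * cbMp + K1 * cbAM - (K4c + K2) * cbAMp;
    double dAM = K2 * cbAMp - (K7c + K1) * cbAM;
    cbMp += dt * dMp; cbAMp += dt * dAMp; cbAM += dt * dAM;
    cbM = 1 - cbMp - cbAMp - cbAM;
    double Fr = (cbAMp + cbAM) / Fr_norm;
    double Ew = E_pas + Fr * (E_act - E_pas);
    double R0w = R0p + Fr * (R0a - R0p);
    R_um += dt * (R0p / eta) * (10 * dpw - Ew * (R_um - R0w) / R0w) * 1e-3;
    t += dt;
    if ((step + 1) % sample_every == 0 && orow < nrow) {
      Ts[orow] = t; Rs[orow] = R_um; Frs[orow] = Fr; ++orow;
    }
  }
  return List::create(_["t_ms"] = Ts, _["R_um"] = Rs, _["F_r"] = Frs,
                      _["Fr_norm"] = Fr_norm);
}
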