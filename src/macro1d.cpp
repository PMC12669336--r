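// 1D pulsatile blood-flow network solver (CGS units).
//
// Conservative cell-centred Richtmyer two-step Lax-Wendroff scheme for
//   dA/dt + dQ/dz = 0
//   dQ/dt + d/dz(Q^2/A + G0/(3 rho sqrt(A0)) A^{3/2}) = -fric * Q/A
// with tube law P(A) = G0 (sqrt(A/A0) - 1) (pressure in barye).
// Boundary interfaces are closed by characteristic compatibility:
// half-sine inflow, 0D Windkessel outlets (RCR), closed ends, and general
// N-way junctions enforcing signed mass conservation and equality of total
// pressure P + rho/2 (Q/A)^2 via damped Newton.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// portable positive modulus (std::fmod resolves to a glibc-2.38-versioned
// symbol under the conda toolchain, absent from older runtime glibc)
inline double pmod(double a, double b) {
  double r = a - std::floor(a / b) * b;
  if (r >= b) r -= b;
  return r;
}

struct Vessel {
  int n;          // number of cells
  double dz, A0, G0, fric; // fric = 2*(gbar+2)*mu/rho  [cm^2/s]
  std::vector<double> A, Q;      // cell values
  std::vector<double> Ah, Qh;    // interface (half-step) values, size n+1
  // boundary interface states (index 0 and n)
  double Ab0, Qb0, AbL, QbL;
};

struct Windkessel {
  double R1, R2, C, pven; // barye*s/cm^3, cm^3/barye, barye
  double p;               // stored pressure state (barye)
};

inline double pressA(double A, double A0, double G0) {
  return G0 * (std::sqrt(A / A0) - 1.0);
}
inline double cspeed(double A, double A0, double G0, double rho) {
  return std::sqrt(G0 / (2.0 * rho)) * std::sqrt(std::sqrt(A / A0));
}
inline double flux2(double A, double Q, double A0, double G0, double rho) {
  return Q * Q / A + G0 / (3.0 * rho * std::sqrt(A0)) * A * std::sqrt(A);
}

// Gaussian elimination with partial pivoting, in-place; x returned in b.
bool gauss_solve(std::vector<double>& M, std::vector<double>& b, int n) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double mx = std::fabs(M[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(M[i * n + k]);
      if (v > mx) { mx = v; piv = i; }
    }
    if (mx < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(M[k * n + j], M[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = M[i * n + k] / M[k * n + k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) M[i * n + j] -= f * M[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= M[i * n + j] * b[j];
    b[i] = s / M[i * n + i];
  }
  return true;
}

// Outgoing characteristic value extrapolated to the foot point.
// side = +1: end z = L (invariant W1 = u + 4c, speed u + c)
// side = -1: end z = 0 (invariant W2 = u - 4c, speed u - c)
double foot_invariant(const Vessel& v, int side, double dt, double rho) {
  int n = v.n;
  double A1, Q1, A2, Q2;
  if (side > 0) { A1 = v.A[n - 1]; Q1 = v.Q[n - 1];
                  A2 = (n > 1) ? v.A[n - 2] : v.A[n - 1];
                  Q2 = (n > 1) ? v.Q[n - 2] : v.Q[n - 1]; }
  else          { A1 = v.A[0]; Q1 = v.Q[0];
                  A2 = (n > 1) ? v.A[1] : v.A[0];
                  Q2 = (n > 1) ? v.Q[1] : v.Q[0]; }
  double u1 = Q1 / A1, u2 = Q2 / A2;
  double c1 = cspeed(A1, v.A0, v.G0, rho), c2 = cspeed(A2, v.A0, v.G0, rho);
  double W1v = (side > 0) ? (u1 + 4.0 * c1) : (u1 - 4.0 * c1);
  double W2v = (side > 0) ? (u2 + 4.0 * c2) : (u2 - 4.0 * c2);
  double lam = (side > 0) ? (u1 + c1) : (u1 - c1);
  double frac = 0.5 - std::fabs(lam) * dt / v.dz; // distance from last cell centre
  return W1v + (W1v - W2v) * frac;
}

// Solve A from invariant equation with Q known:
//   side=+1: Q/A + 4 c(A) = Wf ; side=-1: Q/A - 4 c(A) = Wf
double solve_A_from_invariant(double Q, double Wf, int side,
                              const Vessel& v, double rho) {
  double A = v.A0;
  for (int it = 0; it < 60; ++it) {
    double c = cspeed(A, v.A0, v.G0, rho);
    double f = Q / A + side * 4.0 * c - Wf;
    double df = -Q / (A * A) + side * c / A;
    double step = f / df;
    if (!std::isfinite(step)) break;
    if (std::fabs(step) > 0.5 * A) step = (step > 0 ? 0.5 : -0.5) * A;
    A -= step;
    if (A <= 0) A = 1e-8;
    if (std::fabs(step) < 1e-14 * v.A0) break;
  }
  return A;
}

struct JuncEnd { int vessel; int side; }; // side +1: z=L end, -1: z=0 end

struct Junction {
  std::vector<JuncEnd> ends;
  std::vector<double> sol; // previous (A,Q) pairs as Newton start
};

// Newton solve of junction coupling. Unknowns x = (A_e, Q_e)_e.
// Residuals: per-end characteristic; signed mass; total-pressure equality.
// Returns max |residual| achieved.
double junction_solve(Junction& J, std::vector<Vessel>& ves,
                      double dt, double rho, bool& ok) {
  int N = (int)J.ends.size();
  int m = 2 * N;
  std::vector<double> Wf(N);
  for (int e = 0; e < N; ++e)
    Wf[e] = foot_invariant(ves[J.ends[e].vessel], J.ends[e].side, dt, rho);
  std::vector<double> x = J.sol;
  if ((int)x.size() != m) {
    x.assign(m, 0.0);
    for (int e = 0; e < N; ++e) {
      x[2 * e] = ves[J.ends[e].vessel].A0;
      x[2 * e + 1] = 0.0;
    }
  }
  std::vector<double> R(m), Jac(m * m), dx(m);
  double resn = 0.0;
  for (int it = 0; it < 50; ++it) {
    std::fill(Jac.begin(), Jac.end(), 0.0);
    // characteristic residuals
    for (int e = 0; e < N; ++e) {
      const Vessel& v = ves[J.ends[e].vessel];
      int s = J.ends[e].side;
      double A = x[2 * e], Q = x[2 * e + 1];
      double c = cspeed(A, v.A0, v.G0, rho);
      R[e] = Q / A + s * 4.0 * c - Wf[e];
      Jac[e * m + 2 * e] = -Q / (A * A) + s * c / A;
      Jac[e * m + 2 * e + 1] = 1.0 / A;
    }
    // mass conservation
    int rmass = N;
    R[rmass] = 0.0;
    for (int e = 0; e < N; ++e) {
      double sgn = (J.ends[e].side > 0) ? 1.0 : -1.0;
      R[rmass] += sgn * x[2 * e + 1];
      Jac[rmass * m + 2 * e + 1] = sgn;
    }
    // total pressure equality vs end 0
    const Vessel& v0 = ves[J.ends[0].vessel];
    double A0_ = x[0], Q0_ = x[1];
    double pt0 = pressA(A0_, v0.A0, v0.G0) + 0.5 * rho * (Q0_ / A0_) * (Q0_ / A0_);
    double dpt0_dA = v0.G0 / (2.0 * std::sqrt(A0_ * v0.A0))
      - rho * Q0_ * Q0_ / (A0_ * A0_ * A0_);
    double dpt0_dQ = rho * Q0_ / (A0_ * A0_);
    for (int e = 1; e < N; ++e) {
      const Vessel& v = ves[J.ends[e].vessel];
      double A = x[2 * e], Q = x[2 * e + 1];
      double pt = pressA(A, v.A0, v.G0) + 0.5 * rho * (Q / A) * (Q / A);
      int r = N + e;
      R[r] = pt - pt0;
      Jac[r * m + 2 * e] = v.G0 / (2.0 * std::sqrt(A * v.A0)) - rho * Q * Q / (A * A * A);
      Jac[r * m + 2 * e + 1] = rho * Q / (A * A);
      Jac[r * m + 0] = -dpt0_dA;
      Jac[r * m + 1] = -dpt0_dQ;
    }
    resn = 0.0;
    for (int i = 0; i < m; ++i) resn = std::max(resn, std::fabs(R[i]));
    // scale: characteristic ~ cm/s, pressure ~ barye. relative tol
    if (resn < 1e-10 * (1.0 + std::fabs(pt0)) ) break;
    std::vector<double> Jc = Jac, Rc = R;
    if (!gauss_solve(Jc, Rc, m)) { ok = false; return resn; }
    // damped update keeping A positive
    double damp = 1.0;
    for (int e = 0; e < N; ++e) {
      double Anew = x[2 * e] - Rc[2 * e];
      if (Anew <= 0.1 * ves[J.ends[e].vessel].A0)
        damp = std::min(damp, 0.5 * x[2 * e] / std::max(Rc[2 * e], 1e-300));
    }
    for (int i = 0; i < m; ++i) x[i] -= damp * Rc[i];
  }
  J.sol = x;
  for (int e = 0; e < N; ++e) {
    Vessel& v = ves[J.ends[e].vessel];
    if (J.ends[e].side > 0) { v.AbL = x[2 * e]; v.QbL = x[2 * e + 1]; }
    else                    { v.Ab0 = x[2 * e]; v.Qb0 = x[2 * e + 1]; }
  }
  ok = true;
  return resn;
}

} // namespace

// [[Rcpp::export(name = ".macro1d_run")]]
List macro1d_run(List vessels, List junctions, List bc, List control) {
  // vessels: list of lists with n, dz, A0, G0 (barye), fric, A, Q (init)
  int nv = vessels.size();
  std::vector<Vessel> ves(nv);
  for (int k = 0; k < nv; ++k) {
    List vk = vessels[k];
    Vessel& v = ves[k];
    v.n = as<int>(vk["n"]);
    v.dz = as<double>(vk["dz"]);
    v.A0 = as<double>(vk["A0"]);
    v.G0 = as<double>(vk["G0"]);
    v.fric = as<double>(vk["fric"]);
    NumericVector Ai = vk["A"], Qi = vk["Q"];
    v.A.assign(Ai.begin(), Ai.end());
    v.Q.assign(Qi.begin(), Qi.end());
    v.Ah.assign(v.n + 1, v.A0);
    v.Qh.assign(v.n + 1, 0.0);
    v.Ab0 = v.AbL = v.A0; v.Qb0 = v.QbL = 0.0;
  }
  std::vector<Junction> jun(junctions.size());
  for (int j = 0; j < (int)junctions.size(); ++j) {
    IntegerVector e = junctions[j]; // signed 1-based vessel ids, + => z=L end
    for (int q = 0; q < e.size(); ++q) {
      JuncEnd je; je.vessel = std::abs(e[q]) - 1; je.side = (e[q] > 0) ? 1 : -1;
      jun[j].ends.push_back(je);
    }
  }
  double rho = as<double>(control["rho"]);
  double T = as<double>(control["T"]);
  double dt = as<double>(control["dt"]);
  int steps_per_beat = (int)std::ceil(T / dt - 1e-12);
  dt = T / steps_per_beat;
  int beats_max = as<int>(control["beats_max"]);
  double tol = as<double>(control["tol"]);
  double t_end = as<double>(control["t_end"]); // <=0: run to periodicity

  // BC description
  int inlet_vessel = as<int>(bc["inlet_vessel"]) - 1; // -1 => none
  std::string inlet_type = as<std::string>(bc["inlet_type"]); // "sine"|"closed"
  double Qmax = as<double>(bc["Qmax"]);
  IntegerVector wkv = bc["wk_vessels"]; // 1-based ids with windkessel at z=L
  NumericVector wkR1 = bc["wk_R1"], wkR2 = bc["wk_R2"], wkC = bc["wk_C"],
    wkPven = bc["wk_pven"];
  std::vector<Windkessel> wk(wkv.size());
  std::vector<int> wk_of_vessel(nv, -1);
  for (int i = 0; i < wkv.size(); ++i) {
    wk[i].R1 = wkR1[i]; wk[i].R2 = wkR2[i]; wk[i].C = wkC[i];
    wk[i].pven = wkPven[i]; wk[i].p = wkPven[i];
    wk_of_vessel[wkv[i] - 1] = i;
  }
  // ends not at a junction, not inlet, not windkessel: closed (Q=0) unless
  // listed in bc$periodic_vessels (single-vessel periodic test support)
  IntegerVector pv = bc["periodic_vessels"];
  std::vector<bool> periodic(nv, false);
  for (int i = 0; i < pv.size(); ++i) periodic[pv[i] - 1] = true;
  std::vector<int> end0_junc(nv, -1), endL_junc(nv, -1);
  for (int j = 0; j < (int)jun.size(); ++j)
    for (auto& e : jun[j].ends)
      (e.side > 0 ? endL_junc : end0_junc)[e.vessel] = j;

  // probes: matrix (vessel_id, cell_index 0-based) to record each step
  IntegerMatrix probes = control["probes"]; // ncol = 2
  int np = probes.nrow();
  int max_rec = steps_per_beat + 1;
  NumericMatrix recQ(max_rec, np), recP(max_rec, np), recA(max_rec, np);
  NumericMatrix prevQ(max_rec, np), prevP(max_rec, np);
  NumericVector rec_t(max_rec);

  double t = 0.0;
  int beat = 0;
  bool converged = false;
  double max_junc_res = 0.0;
  double vol_flux_integral = 0.0, vol_start = 0.0;
  double Qin_prev = 0.0, Qout_prev = 0.0;
  bool cfl_fail = false, neg_area = false;

  auto record_row = [&](int row) {
    rec_t[row] = t;
    for (int p = 0; p < np; ++p) {
      const Vessel& v = ves[probes(p, 0) - 1];
      int ci = probes(p, 1);
      if (ci >= v.n) ci = v.n - 1;
      recQ(row, p) = v.Q[ci];
      recA(row, p) = v.A[ci];
      recP(row, p) = pressA(v.A[ci], v.A0, v.G0);
    }
  };

  auto total_volume = [&]() {
    double V = 0.0;
    for (auto& v : ves) for (int i = 0; i < v.n; ++i) V += v.A[i] * v.dz;
    return V;
  };

  int total_steps_limit = (t_end > 0)
    ? (int)std::ceil(t_end / dt) : beats_max * steps_per_beat;
  vol_start = total_volume();
  record_row(0);

  int step_in_beat = 0;
  for (int step = 0; step < total_steps_limit; ++step) {
    // CFL check
    for (auto& v : ves) {
      for (int i = 0; i < v.n; ++i) {
        double c = cspeed(v.A[i], v.A0, v.G0, rho);
        if ((std::fabs(v.Q[i] / v.A[i]) + c) * dt / v.dz > 1.0) cfl_fail = true;
      }
    }
    if (cfl_fail) break;

    // --- boundary interface states at time n (used for fluxes) ---
    // junctions
    for (auto& J : jun) {
      bool ok = true;
      double r = junction_solve(J, ves, dt, rho, ok);
      if (!ok) { neg_area = true; }
      if (r > max_junc_res) max_junc_res = r;
    }
    double tb = t; // boundary fluxes evaluated at current time
    double Qin_now = 0.0;
    for (int k = 0; k < nv; ++k) {
      Vessel& v = ves[k];
      if (periodic[k]) continue;
      // z = 0 end
      if (end0_junc[k] < 0) {
        if (k == inlet_vessel && inlet_type == "sine") {
          double tt = pmod(tb, T);
          double Qb = (tt <= 0.3 * T) ? Qmax * std::sin(M_PI * tt / (0.3 * T)) : 0.0;
          double Wf = foot_invariant(v, -1, dt, rho);
          v.Ab0 = solve_A_from_invariant(Qb, Wf, -1, v, rho);
          v.Qb0 = Qb;
          Qin_now = Qb;
        } else { // closed
          double Wf = foot_invariant(v, -1, dt, rho);
          v.Ab0 = solve_A_from_invariant(0.0, Wf, -1, v, rho);
          v.Qb0 = 0.0;
        }
      }
      // z = L end
      if (endL_junc[k] < 0) {
        int w = wk_of_vessel[k];
        double Wf = foot_invariant(v, +1, dt, rho);
        if (w >= 0) {
          Windkessel& W = wk[w];
          // Newton on A: P(A) - pc(Q(A)) - R1 Q(A) = 0 with implicit pc
          double A = v.AbL;
          double a1 = 1.0 + dt / (W.R2 * W.C);
          for (int it = 0; it < 60; ++it) {
            double c = cspeed(A, v.A0, v.G0, rho);
            double Q = A * (Wf - 4.0 * c);
            double dQ = Wf - 4.0 * c - A * (c / A); // d/dA [A(Wf-4c)]
            double pc = (W.p + dt / W.C * (Q + W.pven / W.R2)) / a1;
            double dpc = (dt / W.C) * dQ / a1;
            double P = pressA(A, v.A0, v.G0);
            double dP = v.G0 / (2.0 * std::sqrt(A * v.A0));
            double f = P - pc - W.R1 * Q;
            double df = dP - dpc - W.R1 * dQ;
            double stepA = f / df;
            if (!std::isfinite(stepA)) break;
            if (std::fabs(stepA) > 0.3 * A) stepA = (stepA > 0 ? 0.3 : -0.3) * A;
            A -= stepA;
            if (A <= 0) A = 0.5 * v.A0;
            if (std::fabs(stepA) < 1e-14 * v.A0) break;
          }
          double c = cspeed(A, v.A0, v.G0, rho);
          double Q = A * (Wf - 4.0 * c);
          W.p = (W.p + dt / W.C * (Q + W.pven / W.R2)) / a1;
          v.AbL = A; v.QbL = Q;
        } else { // closed
          v.AbL = solve_A_from_invariant(0.0, Wf, +1, v, rho);
          v.QbL = 0.0;
        }
      }
    }
    double Qout_now = 0.0;
    for (int k = 0; k < nv; ++k)
      if (wk_of_vessel[k] >= 0) Qout_now += ves[k].QbL;

    // --- Richtmyer half step: interface values ---
    for (auto& v : ves) {
      int n = v.n;
      if (false) {}
      for (int j = 1; j < n; ++j) { // interior interfaces
        double Al = v.A[j - 1], Ql = v.Q[j - 1], Ar = v.A[j], Qr = v.Q[j];
        double Am = 0.5 * (Al + Ar), Qm = 0.5 * (Ql + Qr);
        double F1l = Ql, F1r = Qr;
        double F2l = flux2(Al, Ql, v.A0, v.G0, rho);
        double F2r = flux2(Ar, Qr, v.A0, v.G0, rho);
        double S2 = -v.fric * Qm / Am;
        v.Ah[j] = Am - 0.5 * dt / v.dz * (F1r - F1l);
        v.Qh[j] = Qm - 0.5 * dt / v.dz * (F2r - F2l) + 0.5 * dt * S2;
        if (v.Ah[j] <= 0) { neg_area = true; v.Ah[j] = 1e-8; }
      }
      // boundary interfaces: use solved boundary states
      int k = (int)(&v - &ves[0]);
      if (periodic[k]) {
        // periodic: interface 0 == interface n, computed from cells n-1 and 0
        double Al = v.A[n - 1], Ql = v.Q[n - 1], Ar = v.A[0], Qr = v.Q[0];
        double Am = 0.5 * (Al + Ar), Qm = 0.5 * (Ql + Qr);
        double F2l = flux2(Al, Ql, v.A0, v.G0, rho);
        double F2r = flux2(Ar, Qr, v.A0, v.G0, rho);
        double S2 = -v.fric * Qm / Am;
        v.Ah[0] = v.Ah[n] = Am - 0.5 * dt / v.dz * (Qr - Ql);
        v.Qh[0] = v.Qh[n] = Qm - 0.5 * dt / v.dz * (F2r - F2l) + 0.5 * dt * S2;
      } else {
        v.Ah[0] = v.Ab0; v.Qh[0] = v.Qb0;
        v.Ah[n] = v.AbL; v.Qh[n] = v.QbL;
      }
    }

    // --- full step on cells ---
    for (auto& v : ves) {
      int n = v.n;
      double invdz = 1.0 / v.dz;
      std::vector<double> An(n), Qn(n);
      for (int i = 0; i < n; ++i) {
        double F1l = v.Qh[i], F1r = v.Qh[i + 1];
        double F2l = flux2(v.Ah[i], v.Qh[i], v.A0, v.G0, rho);
        double F2r = flux2(v.Ah[i + 1], v.Qh[i + 1], v.A0, v.G0, rho);
        double Qm = 0.5 * (v.Qh[i] + v.Qh[i + 1]);
        double Am = 0.5 * (v.Ah[i] + v.Ah[i + 1]);
        An[i] = v.A[i] - dt * invdz * (F1r - F1l);
        Qn[i] = v.Q[i] - dt * invdz * (F2r - F2l) - dt * v.fric * Qm / Am;
        if (An[i] <= 0) { neg_area = true; An[i] = 1e-8; }
      }
      v.A.swap(An); v.Q.swap(Qn);
    }

    // trapezoid of boundary flux for volume balance
    if (step > 0) vol_flux_integral += 0.5 * dt * ((Qin_prev + Qin_now)
                                                   - (Qout_prev + Qout_now));
    else vol_flux_integral += 0.5 * dt * (Qin_now - Qout_now);
    Qin_prev = Qin_now; Qout_prev = Qout_now;

    t += dt;
    ++step_in_beat;
    record_row(step_in_beat);

    if (neg_area) break;

    if (step_in_beat == steps_per_beat) {
      // beat finished: periodicity check
      if (t_end <= 0 && beat >= 1) {
        double num = 0.0, den = 0.0;
        for (int p = 0; p < np; ++p) {
          for (int r = 0; r < max_rec; ++r) {
            double dq = recQ(r, p) - prevQ(r, p);
            double dp_ = recP(r, p) - prevP(r, p);
            num += dq * dq + dp_ * dp_;
            den += prevQ(r, p) * prevQ(r, p) + prevP(r, p) * prevP(r, p);
          }
        }
        if (den > 0 && std::sqrt(num / den) < tol) converged = true;
      }
      ++beat;
      if (converged) break;
      if (t_end <= 0 && beat >= beats_max) break;
      for (int p = 0; p < np; ++p)
        for (int r = 0; r < max_rec; ++r) {
          prevQ(r, p) = recQ(r, p); prevP(r, p) = recP(r, p);
        }
      step_in_beat = 0;
      record_row(0);
      vol_flux_integral = 0.0;       // per-beat balance on the last full beat
      vol_start = total_volume();
    }
  }

  double vol_end = total_volume();
  List state(nv);
  for (int k = 0; k < nv; ++k)
    state[k] = List::create(_["A"] = NumericVector(ves[k].A.begin(), ves[k].A.end()),
                            _["Q"] = NumericVector(ves[k].Q.begin(), ves[k].Q.end()));
  NumericVector wkp(wk.size());
  for (int i = 0; i < (int)wk.size(); ++i) wkp[i] = wk[i].p;
  return List::create(
    _["t"] = rec_t, _["Q"] = recQ, _["P"] = recP, _["A"] = recA,
    _["rows_used"] = step_in_beat + 1,
    _["beats"] = beat, _["converged"] = converged,
    _["dt"] = dt, _["steps_per_beat"] = steps_per_beat,
    _["max_junction_residual"] = max_junc_res,
    _["volume_change"] = vol_end - vol_start,
    _["boundary_flux_integral"] = vol_flux_integral,
    _["cfl_violation"] = cfl_fail, _["negative_area"] = neg_area,
    _["wk_pressure"] = wkp, _["state"] = state);
}
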