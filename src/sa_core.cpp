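// Two-step Lax-Wendroff core for the 1D large-artery network.
//
// State (A, Q) per segment; tube law P = P0 + f(r0) (1 - sqrt(A0/A)) with
// f = (4/3)(k1 exp(k2 r0) + k3).  Conservative form
//   A_t + Q_x = 0
//   Q_t + (Q^2/A + B)_x = -(2 pi nu R / delta) Q/A + g_taper
// with B = f sqrt(A0 A)/rho and the taper source
//   g_taper = (2 sqrt(A)(sqrt(pi) f + sqrt(A0) f') - A f') r0'(x) / rho.
// Boundaries (inlet, junctions, terminals) are closed with ghost-point
// characteristic extrapolation: the Riemann-type invariants of the tube law
// are u -/+ 4c along dx/dt = u +/- c (c ~ A^{-1/4} for this wall law).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <complex>
#include <sstream>
using namespace Rcpp;

struct Params {
  double rho, nu, delta, P0, k1, k2, k3, dt, cfl_limit, jtol;
  int jmax;
};

struct Seg {
  int n;
  double dx, L;
  std::vector<double> A, Q;
  std::vector<double> r0, A0, f, dfdr, drdx;      // node geometry
  std::vector<double> r0h, A0h, fh, dfdrh, drdxh; // half-point geometry
  std::vector<double> Ah, Qh;                     // predictor values
  std::vector<double> An, Qn;                     // scratch for update
  int d1 = -1, d2 = -1;
  bool terminal = false;
  std::vector<double> zimp;   // impulse response z(k dt), length N
  std::vector<double> qhist;  // ring buffer of outlet flow, length N
  double out_volume = 0.0;
  double q_out_prev = 0.0;
};

struct SASim {
  Params par;
  std::vector<Seg> segs;
  int root = 0;
  int N = 0;                  // steps per period / convolution length
  double t = 0.0;
  long step = 0;              // completed steps
  double in_volume = 0.0, q_in_prev = 0.0;
  double max_cfl = 0.0;
  double max_jresid = 0.0;    // worst junction residual (relative) last step
  std::vector<double> rec_t, rec_inP, rec_inQ, rec_inA;
  std::vector<double> rec_mid;  // step-major [P1..Pn, Q1..Qn, A1..An]
};

static inline double tubef(const Params& p, double r) {
  return (4.0 / 3.0) * (p.k1 * std::exp(p.k2 * r) + p.k3);
}
static inline double tubedf(const Params& p, double r) {
  return (4.0 / 3.0) * p.k1 * p.k2 * std::exp(p.k2 * r);
}
static inline double pres(const Params& p, double A, double f, double A0) {
  return p.P0 + f * (1.0 - std::sqrt(A0 / A));
}
static inline double wspeed(const Params& p, double A, double f, double A0) {
  return std::sqrt(f / (2.0 * p.rho) * std::sqrt(A0 / A));
}
static inline double fluxQ(const Params& p, double A, double Q, double f, double A0) {
  return Q * Q / A + f * std::sqrt(A0 * A) / p.rho;
}
static inline double srcQ(const Params& p, double A, double Q, double f,
                          double df, double A0, double drdx) {
  double R = std::sqrt(A / M_PI);
  double fric = -2.0 * M_PI * p.nu * R / p.delta * (Q / A);
  double taper = (2.0 * std::sqrt(A) * (std::sqrt(M_PI) * f + std::sqrt(A0) * df)
                  - A * df) * drdx / p.rho;
  return fric + taper;
}

static void build_geometry(Seg& s, const Params& p, double rtop, double rbot) {
  s.dx = s.L / (s.n - 1);
  s.r0.resize(s.n); s.A0.resize(s.n); s.f.resize(s.n);
  s.dfdr.resize(s.n); s.drdx.resize(s.n);
  int nh = s.n - 1;
  s.r0h.resize(nh); s.A0h.resize(nh); s.fh.resize(nh);
  s.dfdrh.resize(nh); s.drdxh.resize(nh);
  double lr = std::log(rbot / rtop) / s.L;   // r0(x) = rtop * exp(lr * x)
  for (int i = 0; i < s.n; ++i) {
    double x = i * s.dx;
    double r = rtop * std::exp(lr * x);
    s.r0[i] = r; s.A0[i] = M_PI * r * r;
    s.f[i] = tubef(p, r); s.dfdr[i] = tubedf(p, r);
    s.drdx[i] = r * lr;
  }
  for (int i = 0; i < nh; ++i) {
    double x = (i + 0.5) * s.dx;
    double r = rtop * std::exp(lr * x);
    s.r0h[i] = r; s.A0h[i] = M_PI * r * r;
    s.fh[i] = tubef(p, r); s.dfdrh[i] = tubedf(p, r);
    s.drdxh[i] = r * lr;
  }
  s.A = s.A0; s.Q.assign(s.n, 0.0);
  s.Ah.resize(nh); s.Qh.resize(nh);
  s.An.resize(s.n); s.Qn.resize(s.n);
}

// ---- interior Lax-Wendroff -------------------------------------------------

static void predictor(SASim& sim, Seg& s, int si) {
  const Params& p = sim.par;
  double lam = p.dt / s.dx;
  for (int j = 0; j < s.n - 1; ++j) {
    double Fl = fluxQ(p, s.A[j], s.Q[j], s.f[j], s.A0[j]);
    double Fr = fluxQ(p, s.A[j + 1], s.Q[j + 1], s.f[j + 1], s.A0[j + 1]);
    double Sl = srcQ(p, s.A[j], s.Q[j], s.f[j], s.dfdr[j], s.A0[j], s.drdx[j]);
    double Sr = srcQ(p, s.A[j + 1], s.Q[j + 1], s.f[j + 1], s.dfdr[j + 1],
                     s.A0[j + 1], s.drdx[j + 1]);
    s.Ah[j] = 0.5 * (s.A[j] + s.A[j + 1]) - 0.5 * lam * (s.Q[j + 1] - s.Q[j]);
    s.Qh[j] = 0.5 * (s.Q[j] + s.Q[j + 1]) - 0.5 * lam * (Fr - Fl)
              + 0.25 * p.dt * (Sl + Sr);
    if (!(s.Ah[j] > 0.0) || !std::isfinite(s.Qh[j])) {
      std::ostringstream os;
      os << "non-finite or collapsed state in segment " << si + 1
         << " near node " << j + 1 << " at t = " << sim.t;
      stop(os.str());
    }
  }
  // CFL monitor on node values
  for (int j = 0; j < s.n; ++j) {
    double c = wspeed(p, s.A[j], s.f[j], s.A0[j]);
    double cfl = (std::fabs(s.Q[j] / s.A[j]) + c) * p.dt / s.dx;
    if (cfl > sim.max_cfl) sim.max_cfl = cfl;
    if (cfl > p.cfl_limit) {
      std::ostringstream os;
      os << "CFL violation in segment " << si + 1 << ": " << cfl
         << " > limit " << p.cfl_limit << " at t = " << sim.t;
      stop(os.str());
    }
  }
}

static void corrector(SASim& sim, Seg& s) {
  const Params& p = sim.par;
  double lam = p.dt / s.dx;
  for (int j = 1; j < s.n - 1; ++j) {
    double Fl = fluxQ(p, s.Ah[j - 1], s.Qh[j - 1], s.fh[j - 1], s.A0h[j - 1]);
    double Fr = fluxQ(p, s.Ah[j], s.Qh[j], s.fh[j], s.A0h[j]);
    double Sl = srcQ(p, s.Ah[j - 1], s.Qh[j - 1], s.fh[j - 1], s.dfdrh[j - 1],
                     s.A0h[j - 1], s.drdxh[j - 1]);
    double Sr = srcQ(p, s.Ah[j], s.Qh[j], s.fh[j], s.dfdrh[j],
                     s.A0h[j], s.drdxh[j]);
    s.An[j] = s.A[j] - lam * (s.Qh[j] - s.Qh[j - 1]);
    s.Qn[j] = s.Q[j] - lam * (Fr - Fl) + 0.5 * p.dt * (Sl + Sr);
  }
}

// ---- conservative ghost-cell boundary closures -----------------------------
//
// Boundary cells have width dx/2.  Their area is advanced by exact mass
// balance: the predictor half-point flux on the interior face and the
// trapezoidal flow (Q^n + Q^{n+1})/2 on the boundary face.  The unknown
// boundary flows follow from Newton iteration on pressure continuity and
// flow conservation at junctions (conservation is then exact by
// construction), on the impedance convolution at terminals, and from the
// prescribed inflow at the root.  Total blood volume is conserved to
// round-off.

// area of a proximal (x = 0) boundary cell given its new face flow q
static inline double prox_area(const Seg& s, const Params& p, double q) {
  return s.A[0] + (2.0 * p.dt / s.dx) * (0.5 * (s.Q[0] + q) - s.Qh[0]);
}
// area of a distal (x = L) boundary cell given its new face flow q
static inline double dist_area(const Seg& s, const Params& p, double q) {
  int m = s.n - 1;
  return s.A[m] + (2.0 * p.dt / s.dx) * (s.Qh[m - 1] - 0.5 * (s.Q[m] + q));
}

static void check_area(double A, const SASim& sim, int si, const char* where) {
  if (!(A > 0.0) || !std::isfinite(A)) {
    std::ostringstream os;
    os << "collapsed boundary cell (" << where << ") in segment " << si + 1
       << " at t = " << sim.t;
    stop(os.str());
  }
}

// bifurcation: unknown daughter flows (q1, q2); parent flow q1 + q2
static void solve_bifurcation(SASim& sim, Seg& sp, Seg& s1, Seg& s2, int si) {
  const Params& p = sim.par;
  int m = sp.n - 1;
  double q1 = s1.Q[0], q2 = s2.Q[0];
  double ps = sp.f[m];
  bool ok = false;
  double F1 = 0, F2 = 0;
  double Ap = sp.A[m], A1 = s1.A[0], A2 = s2.A[0];
  for (int it = 0; it < p.jmax; ++it) {
    Ap = dist_area(sp, p, q1 + q2);
    A1 = prox_area(s1, p, q1);
    A2 = prox_area(s2, p, q2);
    check_area(Ap, sim, si, "junction parent");
    check_area(A1, sim, si, "junction daughter");
    check_area(A2, sim, si, "junction daughter");
    double Pp = pres(p, Ap, sp.f[m], sp.A0[m]);
    F1 = Pp - pres(p, A1, s1.f[0], s1.A0[0]);
    F2 = Pp - pres(p, A2, s2.f[0], s2.A0[0]);
    if (std::fabs(F1) < p.jtol * ps && std::fabs(F2) < p.jtol * ps) {
      ok = true; break;
    }
    double cp = wspeed(p, Ap, sp.f[m], sp.A0[m]);
    double c1 = wspeed(p, A1, s1.f[0], s1.A0[0]);
    double c2 = wspeed(p, A2, s2.f[0], s2.A0[0]);
    double dPp = -(p.rho * cp * cp / Ap) * (p.dt / sp.dx);  // dPp/dq1 = dPp/dq2
    double dP1 = (p.rho * c1 * c1 / A1) * (p.dt / s1.dx);
    double dP2 = (p.rho * c2 * c2 / A2) * (p.dt / s2.dx);
    double a11 = dPp - dP1, a12 = dPp;
    double a21 = dPp, a22 = dPp - dP2;
    double det = a11 * a22 - a12 * a21;
    if (det == 0.0) break;
    q1 += (-F1 * a22 + F2 * a12) / det;
    q2 += (-a11 * F2 + a21 * F1) / det;
  }
  if (!ok) {
    std::ostringstream os;
    os << "junction at segment " << si + 1 << " did not converge: pressure "
       << "residuals " << F1 << "/" << F2 << " at t = " << sim.t;
    stop(os.str());
  }
  double resid = std::max(std::fabs(F1), std::fabs(F2)) / ps;
  if (resid > sim.max_jresid) sim.max_jresid = resid;
  sp.An[m] = Ap; sp.Qn[m] = q1 + q2;
  s1.An[0] = A1; s1.Qn[0] = q1;
  s2.An[0] = A2; s2.Qn[0] = q2;
}

// series connection: one continuing flow, pressure continuity
static void solve_series(SASim& sim, Seg& sp, Seg& s1, int si) {
  const Params& p = sim.par;
  int m = sp.n - 1;
  double q = s1.Q[0];
  double ps = sp.f[m];
  bool ok = false;
  double F = 0, Ap = sp.A[m], A1 = s1.A[0];
  for (int it = 0; it < p.jmax; ++it) {
    Ap = dist_area(sp, p, q);
    A1 = prox_area(s1, p, q);
    check_area(Ap, sim, si, "series parent");
    check_area(A1, sim, si, "series daughter");
    F = pres(p, Ap, sp.f[m], sp.A0[m]) - pres(p, A1, s1.f[0], s1.A0[0]);
    if (std::fabs(F) < p.jtol * ps) { ok = true; break; }
    double cp = wspeed(p, Ap, sp.f[m], sp.A0[m]);
    double c1 = wspeed(p, A1, s1.f[0], s1.A0[0]);
    double dF = -(p.rho * cp * cp / Ap) * (p.dt / sp.dx)
                - (p.rho * c1 * c1 / A1) * (p.dt / s1.dx);
    q -= F / dF;
  }
  if (!ok) {
    std::ostringstream os;
    os << "series junction at segment " << si + 1
       << " did not converge at t = " << sim.t;
    stop(os.str());
  }
  double resid = std::fabs(F) / ps;
  if (resid > sim.max_jresid) sim.max_jresid = resid;
  sp.An[m] = Ap; sp.Qn[m] = q;
  s1.An[0] = A1; s1.Qn[0] = q;
}

// terminal: tube-law pressure equals the periodic impedance convolution
static void solve_terminal(SASim& sim, Seg& s, int si) {
  const Params& p = sim.par;
  int m = s.n - 1;
  const int N = sim.N;
  double hist = 0.0;
  long next = (sim.step + 1) % N;   // slot of Q^{n+1}
  for (int k = 1; k < N; ++k) {
    long idx = next - k; idx %= N; if (idx < 0) idx += N;
    hist += s.zimp[k] * s.qhist[idx];
  }
  hist *= p.dt;
  double z0dt = s.zimp[0] * p.dt;
  double q = s.Q[m];
  bool ok = false;
  double A = s.A[m];
  for (int it = 0; it < p.jmax; ++it) {
    A = dist_area(s, p, q);
    check_area(A, sim, si, "terminal");
    double g = pres(p, A, s.f[m], s.A0[m]) - p.P0 - z0dt * q - hist;
    if (std::fabs(g) < p.jtol * s.f[m]) { ok = true; break; }
    double c = wspeed(p, A, s.f[m], s.A0[m]);
    double dg = -(p.rho * c * c / A) * (p.dt / s.dx) - z0dt;
    q -= g / dg;
  }
  if (!ok) {
    std::ostringstream os;
    os << "terminal boundary of segment " << si + 1
       << " did not converge at t = " << sim.t;
    stop(os.str());
  }
  s.An[m] = A; s.Qn[m] = q;
  s.qhist[next] = q;
  s.out_volume += 0.5 * p.dt * (q + s.q_out_prev);
  s.q_out_prev = q;
}

// ---- one full step ---------------------------------------------------------

static void do_step(SASim& sim, double qin, bool interior_only) {
  int ns = (int)sim.segs.size();
  sim.max_jresid = 0.0;
  for (int i = 0; i < ns; ++i) predictor(sim, sim.segs[i], i);
  for (int i = 0; i < ns; ++i) {
    corrector(sim, sim.segs[i]);
    // default: keep boundary nodes (overwritten below unless interior_only)
    sim.segs[i].An[0] = sim.segs[i].A[0];
    sim.segs[i].Qn[0] = sim.segs[i].Q[0];
    sim.segs[i].An[sim.segs[i].n - 1] = sim.segs[i].A[sim.segs[i].n - 1];
    sim.segs[i].Qn[sim.segs[i].n - 1] = sim.segs[i].Q[sim.segs[i].n - 1];
  }
  if (!interior_only) {
    Seg& rt = sim.segs[sim.root];
    double Ain = prox_area(rt, sim.par, qin);
    check_area(Ain, sim, sim.root, "inlet");
    rt.An[0] = Ain; rt.Qn[0] = qin;
    sim.in_volume += 0.5 * sim.par.dt * (qin + sim.q_in_prev);
    sim.q_in_prev = qin;
    for (int i = 0; i < ns; ++i) {
      Seg& s = sim.segs[i];
      if (s.terminal) {
        solve_terminal(sim, s, i);
      } else if (s.d2 >= 0) {
        solve_bifurcation(sim, s, sim.segs[s.d1], sim.segs[s.d2], i);
      } else {
        solve_series(sim, s, sim.segs[s.d1], i);
      }
    }
  }
  for (int i = 0; i < ns; ++i) {
    sim.segs[i].A.swap(sim.segs[i].An);
    sim.segs[i].Q.swap(sim.segs[i].Qn);
  }
  sim.t += sim.par.dt;
  sim.step += 1;
  // record probes (segment midpoints) and the root inlet
  sim.rec_t.push_back(sim.t);
  Seg& rt = sim.segs[sim.root];
  sim.rec_inP.push_back(pres(sim.par, rt.A[0], rt.f[0], rt.A0[0]));
  sim.rec_inQ.push_back(rt.Q[0]);
  sim.rec_inA.push_back(rt.A[0]);
  for (int i = 0; i < ns; ++i) {
    Seg& s = sim.segs[i];
    int mid = (s.n - 1) / 2;
    sim.rec_mid.push_back(pres(sim.par, s.A[mid], s.f[mid], s.A0[mid]));
    sim.rec_mid.push_back(s.Q[mid]);
    sim.rec_mid.push_back(s.A[mid]);
  }
}

// ---- R interface -----------------------------------------------------------

typedef XPtr<SASim> SimPtr;

// [[Rcpp::export]]
SEXP sa_create_(List segments, List params, int n_period) {
  SASim* sim = new SASim();
  sim->par.rho = as<double>(params["rho"]);
  sim->par.nu = as<double>(params["nu"]);
  sim->par.delta = as<double>(params["delta_star"]);
  sim->par.P0 = as<double>(params["P0"]);
  sim->par.k1 = as<double>(params["k1"]);
  sim->par.k2 = as<double>(params["k2"]);
  sim->par.k3 = as<double>(params["k3"]);
  sim->par.dt = as<double>(params["dt"]);
  sim->par.cfl_limit = as<double>(params["cfl_limit"]);
  sim->par.jtol = as<double>(params["junction_tolerance"]);
  sim->par.jmax = as<int>(params["max_junction_iters"]);
  sim->N = n_period;
  int ns = segments.size();
  sim->segs.resize(ns);
  for (int i = 0; i < ns; ++i) {
    List sl = segments[i];
    Seg& s = sim->segs[i];
    s.L = as<double>(sl["length"]);
    s.n = as<int>(sl["n"]);
    s.d1 = as<int>(sl["d1"]);   // 0-based, -1 if none
    s.d2 = as<int>(sl["d2"]);
    s.terminal = as<bool>(sl["terminal"]);
    build_geometry(s, sim->par, as<double>(sl["r_top"]), as<double>(sl["r_bottom"]));
    if (s.terminal) {
      NumericVector z = sl["zimp"];
      if ((int)z.size() != n_period) stop("impulse response length must equal n_period");
      s.zimp.assign(z.begin(), z.end());
      s.qhist.assign(n_period, 0.0);
    }
  }
  sim->root = as<int>(params["root"]);
  return SimPtr(sim, true);
}

// [[Rcpp::export]]
void sa_step_(SEXP ptr, double qin, bool interior_only = false) {
  SimPtr sim(ptr);
  do_step(*sim, qin, interior_only);
}

// [[Rcpp::export]]
void sa_run_(SEXP ptr, NumericVector qin) {
  SimPtr sim(ptr);
  for (R_xlen_t i = 0; i < qin.size(); ++i) do_step(*sim, qin[i], false);
}

// [[Rcpp::export]]
double sa_root_pressure_(SEXP ptr) {
  SimPtr sim(ptr);
  Seg& rt = sim->segs[sim->root];
  return pres(sim->par, rt.A[0], rt.f[0], rt.A0[0]);
}

// hypothetical inlet pressure at t+dt if the inflow were q (state untouched)
// [[Rcpp::export]]
double sa_inlet_pressure_(SEXP ptr, double q) {
  SimPtr sim(ptr);
  Seg& rt = sim->segs[sim->root];
  const Params& p = sim->par;
  // predictor half-point flux adjacent to the inlet, from the current state
  double Fl = fluxQ(p, rt.A[0], rt.Q[0], rt.f[0], rt.A0[0]);
  double Fr = fluxQ(p, rt.A[1], rt.Q[1], rt.f[1], rt.A0[1]);
  double Sl = srcQ(p, rt.A[0], rt.Q[0], rt.f[0], rt.dfdr[0], rt.A0[0], rt.drdx[0]);
  double Sr = srcQ(p, rt.A[1], rt.Q[1], rt.f[1], rt.dfdr[1], rt.A0[1], rt.drdx[1]);
  double qh0 = 0.5 * (rt.Q[0] + rt.Q[1]) - 0.5 * (p.dt / rt.dx) * (Fr - Fl)
               + 0.25 * p.dt * (Sl + Sr);
  double A = rt.A[0] + (2.0 * p.dt / rt.dx) * (0.5 * (rt.Q[0] + q) - qh0);
  if (!(A > 0.0)) stop("inlet cell collapsed for candidate inflow");
  return pres(p, A, rt.f[0], rt.A0[0]);
}

// [[Rcpp::export]]
List sa_series_(SEXP ptr) {
  SimPtr sim(ptr);
  int ns = (int)sim->segs.size();
  R_xlen_t nt = (R_xlen_t)sim->rec_t.size();
  NumericMatrix P(nt, ns), Q(nt, ns), A(nt, ns);
  for (R_xlen_t k = 0; k < nt; ++k) {
    for (int i = 0; i < ns; ++i) {
      P(k, i) = sim->rec_mid[(k * ns + i) * 3 + 0];
      Q(k, i) = sim->rec_mid[(k * ns + i) * 3 + 1];
      A(k, i) = sim->rec_mid[(k * ns + i) * 3 + 2];
    }
  }
  return List::create(
    _["t"] = NumericVector(sim->rec_t.begin(), sim->rec_t.end()),
    _["P"] = P, _["Q"] = Q, _["A"] = A,
    _["inlet_P"] = NumericVector(sim->rec_inP.begin(), sim->rec_inP.end()),
    _["inlet_Q"] = NumericVector(sim->rec_inQ.begin(), sim->rec_inQ.end()),
    _["inlet_A"] = NumericVector(sim->rec_inA.begin(), sim->rec_inA.end()));
}

// [[Rcpp::export]]
void sa_clear_series_(SEXP ptr) {
  SimPtr sim(ptr);
  sim->rec_t.clear(); sim->rec_mid.clear();
  sim->rec_inP.clear(); sim->rec_inQ.clear(); sim->rec_inA.clear();
}

// [[Rcpp::export]]
List sa_diag_(SEXP ptr) {
  SimPtr sim(ptr);
  int ns = (int)sim->segs.size();
  NumericVector outv(ns);
  for (int i = 0; i < ns; ++i) outv[i] = sim->segs[i].out_volume;
  return List::create(
    _["t"] = sim->t, _["step"] = (double)sim->step,
    _["max_cfl"] = sim->max_cfl, _["max_junction_residual"] = sim->max_jresid,
    _["in_volume"] = sim->in_volume, _["out_volume"] = outv);
}

// [[Rcpp::export]]
void sa_reset_volumes_(SEXP ptr) {
  SimPtr sim(ptr);
  sim->in_volume = 0.0;
  for (size_t i = 0; i < sim->segs.size(); ++i) sim->segs[i].out_volume = 0.0;
}

// [[Rcpp::export]]
List sa_state_get_(SEXP ptr) {
  SimPtr sim(ptr);
  int ns = (int)sim->segs.size();
  List st(ns);
  for (int i = 0; i < ns; ++i) {
    Seg& s = sim->segs[i];
    st[i] = List::create(
      _["A"] = NumericVector(s.A.begin(), s.A.end()),
      _["Q"] = NumericVector(s.Q.begin(), s.Q.end()),
      _["qhist"] = s.terminal ? NumericVector(s.qhist.begin(), s.qhist.end())
                              : NumericVector(0),
      _["q_out_prev"] = s.q_out_prev);
  }
  return List::create(_["segs"] = st, _["t"] = sim->t,
                      _["step"] = (double)sim->step,
                      _["q_in_prev"] = sim->q_in_prev);
}

// [[Rcpp::export]]
void sa_state_set_(SEXP ptr, List state) {
  SimPtr sim(ptr);
  List st = state["segs"];
  int ns = (int)sim->segs.size();
  if (st.size() != ns) stop("state does not match network");
  for (int i = 0; i < ns; ++i) {
    List sl = st[i];
    Seg& s = sim->segs[i];
    NumericVector A = sl["A"], Q = sl["Q"];
    if ((int)A.size() != s.n) stop("state grid mismatch");
    s.A.assign(A.begin(), A.end());
    s.Q.assign(Q.begin(), Q.end());
    if (s.terminal) {
      NumericVector qh = sl["qhist"];
      s.qhist.assign(qh.begin(), qh.end());
      s.q_out_prev = as<double>(sl["q_out_prev"]);
    }
  }
  sim->t = as<double>(state["t"]);
  sim->step = (long)as<double>(state["step"]);
  sim->q_in_prev = as<double>(state["q_in_prev"]);
}

// node coordinates and state snapshot, for inspection/tests
// [[Rcpp::export]]
List sa_snapshot_(SEXP ptr, int seg) {
  SimPtr sim(ptr);
  Seg& s = sim->segs[seg];
  int n = s.n;
  NumericVector x(n), A(n), Q(n), P(n), r0(n);
  for (int i = 0; i < n; ++i) {
    x[i] = i * s.dx; A[i] = s.A[i]; Q[i] = s.Q[i]; r0[i] = s.r0[i];
    P[i] = pres(sim->par, s.A[i], s.f[i], s.A0[i]);
  }
  return List::create(_["x"] = x, _["A"] = A, _["Q"] = Q, _["P"] = P,
                      _["r0"] = r0, _["dx"] = s.dx);
}

// overwrite state of one segment (tests construct pulses this way)
// [[Rcpp::export]]
void sa_set_state_(SEXP ptr, int seg, NumericVector A, NumericVector Q) {
  SimPtr sim(ptr);
  Seg& s = sim->segs[seg];
  if ((int)A.size() != s.n || (int)Q.size() != s.n) stop("grid mismatch");
  s.A.assign(A.begin(), A.end());
  s.Q.assign(Q.begin(), Q.end());
}

// ---- Womersley friction function -------------------------------------------

// F10(w) = 2 J1(z)/(z J0(z)) with z = i^{3/2} w; the Bessel ratio is computed
// with a modified Lentz continued fraction, stable for all |z|.
// [[Rcpp::export]]
ComplexVector womersley_f10(NumericVector w) {
  const std::complex<double> i32 = std::polar(1.0, 3.0 * M_PI / 4.0);
  R_xlen_t n = w.size();
  ComplexVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    std::complex<double> F;
    double wk = w[k];
    if (wk < 1e-6) {
      std::complex<double> z2 = i32 * i32 * wk * wk;
      F = 1.0 + z2 / 8.0;   // small-argument series: F = 1 + z^2/8 + O(z^4)
    } else {
      std::complex<double> z = i32 * wk;
      // Lentz for r = J1/J0 = 1/(2/z - 1/(4/z - 1/(6/z - ...)))
      const double tiny = 1e-300;
      std::complex<double> b = 2.0 / z;
      std::complex<double> fv = b; if (std::abs(fv) < tiny) fv = tiny;
      std::complex<double> C = fv, D = 0.0;
      for (int m = 2; m < 100000; ++m) {
        b = 2.0 * m / z;
        D = b - D; if (std::abs(D) < tiny) D = tiny;
        C = b - 1.0 / C; if (std::abs(C) < tiny) C = tiny;
        D = 1.0 / D;
        std::complex<double> delta = C * D;
        fv *= delta;
        if (std::abs(delta - 1.0) < 1e-15) break;
      }
      std::complex<double> ratio = 1.0 / fv;   // J1/J0
      F = 2.0 * ratio / z;
    }
    out[k] = Rcomplex{F.real(), F.imag()};
  }
  return out;
}
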