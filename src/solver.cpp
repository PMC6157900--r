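// 1D pulse wave propagation on a bifurcating arterial tree.
//
// Conservation form on (A, q) per vessel:
//   A_t + q_x = 0
//   q_t + (q^2/A + B)_x = S,  B = f(x) sqrt(A0(x) A) / rho
//   S = -(2 pi nu r / delta) (q/A)
//       + (1/rho) (2 sqrt(pi A) f + (2 sqrt(pi) r0 sqrt(A) - A) f') dr0/dx
// closed by the tube law p = p_ref + f (1 - sqrt(A0/A)), with
// c(A) = sqrt(f/(2 rho)) (A0/A)^{1/4}.
//
// Interior: two-step (Richtmyer) Lax-Wendroff. Boundaries: conservative
// half-cell finite-volume updates of the boundary areas (using the
// time-averaged boundary flux), coupled by Newton solves to the boundary
// relations: prescribed root inflow; flow conservation and pressure
// continuity at junctions; three-element Windkessel at terminals, optionally
// in parallel with a lumped arteriovenous fistula branch draining to a
// venous Windkessel. Total blood volume then balances the boundary flux
// integrals exactly (to Newton tolerance).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Endpt {
  double f, A0, sqA0, c0, dfdr, r0;
};

struct WK {
  double R1, R2, C, pout;
  double pc; // capacitor pressure state
};

struct Fistula {
  bool active = false;
  double Rf = 0, R1v = 0, R2v = 0, Cv = 0, poutv = 0;
  double pc = 0;
};

struct Vessel {
  int N;
  double dx, dr0dx;
  std::vector<double> f, dfdr, r0, A0, sqA0, c0n; // nodes
  std::vector<double> fh, dfdrh, r0h, A0h, sqA0h; // half nodes
  std::vector<double> A, Q, Anew, Qnew, Ah, Qh;
  int d1 = -1, d2 = -1;
  bool terminal = false;
  WK wk;
  Fistula fist;
};

static const double PI_ = 3.14159265358979323846;

struct Solver {
  std::vector<Vessel> V;
  double rho, mu, nu, delta, pref, dt, tol;
  int nsteps, n_out, max_cycles, root;
  bool total_pressure;
  NumericVector inflow;

  double pA(const Endpt& e, double A) const {
    return pref + e.f * (1.0 - e.sqA0 / std::sqrt(A));
  }
  double dpdA(const Endpt& e, double A) const {
    return e.f * e.sqA0 / (2.0 * A * std::sqrt(A));
  }
  double cA(const Endpt& e, double A) const {
    return e.c0 * std::sqrt(std::sqrt(e.A0 / A));
  }

  Endpt endpt(const Vessel& v, int j) const {
    Endpt e;
    e.f = v.f[j]; e.A0 = v.A0[j]; e.sqA0 = v.sqA0[j]; e.c0 = v.c0n[j];
    e.dfdr = v.dfdr[j]; e.r0 = v.r0[j];
    return e;
  }

  double source2(double A, double q, double f, double dfdr, double r0,
                 double dr0dx) const {
    double r = std::sqrt(A / PI_);
    double fric = -(2.0 * PI_ * nu * r / delta) * (q / A);
    double geo = (1.0 / rho) *
      (2.0 * std::sqrt(PI_ * A) * f +
       (2.0 * std::sqrt(PI_) * r0 * std::sqrt(A) - A) * dfdr) * dr0dx;
    return fric + geo;
  }

  void interior(Vessel& v) {
    int N = v.N;
    double dtdx = dt / v.dx;
    // half step
    for (int j = 0; j < N - 1; j++) {
      double Am = 0.5 * (v.A[j] + v.A[j + 1]);
      double Qm = 0.5 * (v.Q[j] + v.Q[j + 1]);
      double F2j = v.Q[j] * v.Q[j] / v.A[j] +
        v.f[j] * v.sqA0[j] * std::sqrt(v.A[j]) / rho;
      double F2j1 = v.Q[j + 1] * v.Q[j + 1] / v.A[j + 1] +
        v.f[j + 1] * v.sqA0[j + 1] * std::sqrt(v.A[j + 1]) / rho;
      double Sh = source2(Am, Qm, v.fh[j], v.dfdrh[j], v.r0h[j], v.dr0dx);
      v.Ah[j] = Am - 0.5 * dtdx * (v.Q[j + 1] - v.Q[j]);
      v.Qh[j] = Qm - 0.5 * dtdx * (F2j1 - F2j) + 0.5 * dt * Sh;
      if (!(v.Ah[j] > 0.0)) stop("instability: non-positive area (half step)");
    }
    // full step, interior nodes
    for (int j = 1; j < N - 1; j++) {
      double F2l = v.Qh[j - 1] * v.Qh[j - 1] / v.Ah[j - 1] +
        v.fh[j - 1] * v.sqA0h[j - 1] * std::sqrt(v.Ah[j - 1]) / rho;
      double F2r = v.Qh[j] * v.Qh[j] / v.Ah[j] +
        v.fh[j] * v.sqA0h[j] * std::sqrt(v.Ah[j]) / rho;
      double Sl = source2(v.Ah[j - 1], v.Qh[j - 1], v.fh[j - 1],
                          v.dfdrh[j - 1], v.r0h[j - 1], v.dr0dx);
      double Sr = source2(v.Ah[j], v.Qh[j], v.fh[j], v.dfdrh[j], v.r0h[j],
                          v.dr0dx);
      v.Anew[j] = v.A[j] - dtdx * (v.Qh[j] - v.Qh[j - 1]);
      v.Qnew[j] = v.Q[j] - dtdx * (F2r - F2l) + 0.5 * dt * (Sl + Sr);
      if (!(v.Anew[j] > 0.0) || !std::isfinite(v.Qnew[j]))
        stop("instability: non-positive area or non-finite flow");
    }
  }

  // linear outflow q(p) through a series resistance into a Windkessel
  // capacitor updated implicitly: returns coefficients q = a * p + b and the
  // implicit-update helper alpha.
  void wk_coef(const WK& w, double Rser, double& a, double& b,
               double& alpha) const {
    alpha = 1.0 / (1.0 + dt / (w.R2 * w.C));
    double denom = Rser + alpha * dt / w.C;
    a = 1.0 / denom;
    b = -(alpha * w.pc + alpha * dt * w.pout / (w.R2 * w.C)) / denom;
  }

  void solve_inlet(Vessel& v, double qin) {
    // conservative half-cell update of the inlet area with the prescribed
    // flow; flux over the step approximated by the trapezoid average
    double qbar = 0.5 * (v.Q[0] + qin);
    double A = v.A[0] - (2.0 * dt / v.dx) * (v.Qh[0] - qbar);
    if (!(A > 0)) stop("inlet solve: non-positive area");
    v.Anew[0] = A; v.Qnew[0] = qin;
  }

  void solve_terminal(Vessel& v) {
    Endpt e = endpt(v, v.N - 1);
    double a1, b1, al1, a2 = 0, b2 = 0, al2 = 0;
    wk_coef(v.wk, v.wk.R1, a1, b1, al1);
    WK wv; // fistula venous chain reuses the same linearisation
    if (v.fist.active) {
      wv.R1 = v.fist.R1v; wv.R2 = v.fist.R2v; wv.C = v.fist.Cv;
      wv.pout = v.fist.poutv; wv.pc = v.fist.pc;
      wk_coef(wv, v.fist.Rf + v.fist.R1v, a2, b2, al2);
    }
    double a = a1 + a2, b = b1 + b2;
    int N = v.N;
    double An = v.A[N - 1], qn = v.Q[N - 1];
    double bet = dt / v.dx;
    double A = An;
    for (int it = 0; it < 80; it++) {
      double p = pA(e, A);
      double qout = a * p + b;
      double g = A - An + 2.0 * bet * (0.5 * (qn + qout) - v.Qh[N - 2]);
      double dg = 1.0 + bet * a * dpdA(e, A);
      double step = g / dg;
      if (step > 0.25 * A) step = 0.25 * A;
      if (step < -0.25 * A) step = -0.25 * A;
      A -= step;
      if (!(A > 0)) stop("terminal solve: non-positive area");
      if (std::fabs(g) < 1e-12 * A) break;
    }
    double p = pA(e, A);
    v.Anew[N - 1] = A; v.Qnew[N - 1] = a * p + b;
    double qwk = a1 * p + b1;
    v.wk.pc = al1 * (v.wk.pc + dt * qwk / v.wk.C +
                     dt * v.wk.pout / (v.wk.R2 * v.wk.C));
    if (v.fist.active) {
      double qf = a2 * p + b2;
      v.fist.pc = al2 * (v.fist.pc + dt * qf / v.fist.Cv +
                         dt * v.fist.poutv / (v.fist.R2v * v.fist.Cv));
    }
  }

  void solve3(double J[3][3], double F[3], double dx_[3]) const {
    // Gaussian elimination with partial pivoting, 3x3
    int idx[3] = {0, 1, 2};
    double M[3][4];
    for (int i = 0; i < 3; i++) {
      for (int j = 0; j < 3; j++) M[i][j] = J[i][j];
      M[i][3] = -F[i];
    }
    for (int k = 0; k < 2; k++) {
      int piv = k;
      for (int i = k + 1; i < 3; i++)
        if (std::fabs(M[i][k]) > std::fabs(M[piv][k])) piv = i;
      if (piv != k) for (int j = k; j < 4; j++) std::swap(M[k][j], M[piv][j]);
      (void)idx;
      for (int i = k + 1; i < 3; i++) {
        double m = M[i][k] / M[k][k];
        for (int j = k; j < 4; j++) M[i][j] -= m * M[k][j];
      }
    }
    dx_[2] = M[2][3] / M[2][2];
    dx_[1] = (M[1][3] - M[1][2] * dx_[2]) / M[1][1];
    dx_[0] = (M[0][3] - M[0][1] * dx_[1] - M[0][2] * dx_[2]) / M[0][0];
  }

  // two-unknown Newton on the daughter flows; parent flow is their sum, so
  // discrete flow conservation is exact by construction. Boundary areas are
  // affine in the new flows through the conservative half-cell updates.
  void solve_junction(Vessel& p, Vessel& a, Vessel& b) {
    Endpt ep = endpt(p, p.N - 1), ea = endpt(a, 0), eb = endpt(b, 0);
    double bp = dt / p.dx, ba = dt / a.dx, bb = dt / b.dx;
    double alp = p.A[p.N - 1] - bp * p.Q[p.N - 1] + 2.0 * bp * p.Qh[p.N - 2];
    double ala = a.A[0] + ba * a.Q[0] - 2.0 * ba * a.Qh[0];
    double alb = b.A[0] + bb * b.Q[0] - 2.0 * bb * b.Qh[0];
    double qa = a.Q[0], qb = b.Q[0];
    double Ap = 0, Aa = 0, Ab = 0;
    for (int it = 0; it < 100; it++) {
      Ap = alp - bp * (qa + qb); Aa = ala + ba * qa; Ab = alb + bb * qb;
      if (!(Ap > 0) || !(Aa > 0) || !(Ab > 0))
        stop("junction solve: non-positive area");
      double Pp = pA(ep, Ap), Pa = pA(ea, Aa), Pb = pA(eb, Ab);
      double dPp = dpdA(ep, Ap), dPa = dpdA(ea, Aa), dPb = dpdA(eb, Ab);
      double up = (qa + qb) / Ap, ua = qa / Aa, ub = qb / Ab;
      double dPp_qa = -bp * dPp, dPa_qa = ba * dPa, dPb_qb = bb * dPb;
      double gPp_qa = dPp_qa, gPa_qa = dPa_qa, gPb_qb = dPb_qb;
      if (total_pressure) {
        Pp += 0.5 * rho * up * up; Pa += 0.5 * rho * ua * ua;
        Pb += 0.5 * rho * ub * ub;
        // d(q/A)/dq with A affine in q
        double dup = (Ap + (qa + qb) * bp) / (Ap * Ap);
        double dua = (Aa - qa * ba) / (Aa * Aa);
        double dub = (Ab - qb * bb) / (Ab * Ab);
        gPp_qa = dPp_qa + rho * up * dup;
        gPa_qa = dPa_qa + rho * ua * dua;
        gPb_qb = dPb_qb + rho * ub * dub;
      }
      double F1 = Pp - Pa, F2 = Pp - Pb;
      double scale = ep.f * 1e-9;
      if (std::fabs(F1) < scale && std::fabs(F2) < scale) break;
      double J11 = gPp_qa - gPa_qa, J12 = gPp_qa;
      double J21 = gPp_qa, J22 = gPp_qa - gPb_qb;
      double det = J11 * J22 - J12 * J21;
      double dqa = (-F1 * J22 + F2 * J12) / det;
      double dqb = (-J11 * F2 + J21 * F1) / det;
      double lim = 1.0, cap = 50.0 + 0.5 * (std::fabs(qa) + std::fabs(qb));
      if (std::fabs(dqa) > cap) lim = std::min(lim, cap / std::fabs(dqa));
      if (std::fabs(dqb) > cap) lim = std::min(lim, cap / std::fabs(dqb));
      qa += lim * dqa; qb += lim * dqb;
    }
    p.Anew[p.N - 1] = Ap; p.Qnew[p.N - 1] = qa + qb;
    a.Anew[0] = Aa; a.Qnew[0] = qa;
    b.Anew[0] = Ab; b.Qnew[0] = qb;
  }

  // junction with a single daughter plus a lumped fistula branch
  void solve_fistula_junction(Vessel& p, Vessel& a) {
    Endpt ep = endpt(p, p.N - 1), ea = endpt(a, 0);
    WK wv;
    wv.R1 = p.fist.R1v; wv.R2 = p.fist.R2v; wv.C = p.fist.Cv;
    wv.pout = p.fist.poutv; wv.pc = p.fist.pc;
    double af, bf, alf;
    wk_coef(wv, p.fist.Rf + p.fist.R1v, af, bf, alf);
    double bp = dt / p.dx, ba = dt / a.dx;
    double alp = p.A[p.N - 1] - bp * p.Q[p.N - 1] + 2.0 * bp * p.Qh[p.N - 2];
    double ala = a.A[0] + ba * a.Q[0] - 2.0 * ba * a.Qh[0];
    double qp = p.Q[p.N - 1], qa = a.Q[0];
    double Ap = 0, Aa = 0;
    for (int it = 0; it < 100; it++) {
      Ap = alp - bp * qp; Aa = ala + ba * qa;
      if (!(Ap > 0) || !(Aa > 0))
        stop("fistula junction solve: non-positive area");
      double Pp = pA(ep, Ap), Pa = pA(ea, Aa);
      double F0 = qp - qa - (af * Pp + bf);
      double F1 = Pp - Pa;
      if (std::fabs(F0) < 1e-10 * (1.0 + std::fabs(qp)) &&
          std::fabs(F1) < ep.f * 1e-9) break;
      double J00 = 1.0 + af * bp * dpdA(ep, Ap);
      double J01 = -1.0;
      double J10 = -bp * dpdA(ep, Ap);
      double J11 = -ba * dpdA(ea, Aa);
      double det = J00 * J11 - J01 * J10;
      double dqp = (-F0 * J11 + F1 * J01) / det;
      double dqa = (-J00 * F1 + J10 * F0) / det;
      qp += dqp; qa += dqa;
    }
    double Pp = pA(ep, Ap);
    double qf = af * Pp + bf;
    p.Anew[p.N - 1] = Ap; p.Qnew[p.N - 1] = qp;
    a.Anew[0] = Aa; a.Qnew[0] = qp - qf; // exact discrete conservation
    p.fist.pc = alf * (p.fist.pc + dt * qf / p.fist.Cv +
                       dt * p.fist.poutv / (p.fist.R2v * p.fist.Cv));
  }

  void step(int k_in_cycle) {
    double qin = inflow[k_in_cycle + 1];
    size_t nv = V.size();
    for (size_t i = 0; i < nv; i++) interior(V[i]);
    solve_inlet(V[root], qin);
    for (size_t i = 0; i < nv; i++) {
      Vessel& v = V[i];
      if (v.terminal) solve_terminal(v);
      else if (v.d2 >= 0) solve_junction(v, V[v.d1], V[v.d2]);
      else solve_fistula_junction(v, V[v.d1]);
    }
    for (size_t i = 0; i < nv; i++) {
      Vessel& v = V[i];
      std::swap(v.A, v.Anew); std::swap(v.Q, v.Qnew);
    }
    // CFL audit (cheap cadence; an incipient violation persists for many
    // steps at these time scales)
    if (k_in_cycle % 8 == 0) {
      for (size_t i = 0; i < nv; i++) {
        Vessel& v = V[i];
        for (int j = 0; j < v.N; j++) {
          double c = v.c0n[j] * std::sqrt(std::sqrt(v.A0[j] / v.A[j]));
          double sp = std::fabs(v.Q[j] / v.A[j]) + c;
          if (sp * dt > v.dx)
            stop("CFL violated during run (speed %.1f cm/s > dx/dt at vessel "
                 "%d node %d of %d; A/A0 %.3f, u %.1f); use a smaller time "
                 "step", sp, (int)i + 1, j, v.N, v.A[j] / v.A0[j],
                 v.Q[j] / v.A[j]);
        }
      }
    }
  }

  double volume() const {
    double vol = 0;
    for (size_t i = 0; i < V.size(); i++) {
      const Vessel& v = V[i];
      for (int j = 0; j < v.N - 1; j++)
        vol += 0.5 * (v.A[j] + v.A[j + 1]) * v.dx;
    }
    return vol;
  }
};

// [[Rcpp::export(name = ".pw_solve")]]
List pw_solve(List vessels, List numerics) {
  Solver S;
  S.rho = as<double>(numerics["rho"]);
  S.mu = as<double>(numerics["mu"]);
  S.nu = S.mu / S.rho;
  S.delta = as<double>(numerics["delta"]);
  S.pref = as<double>(numerics["pref"]);
  S.dt = as<double>(numerics["dt"]);
  S.nsteps = as<int>(numerics["nsteps"]);
  S.n_out = as<int>(numerics["n_out"]);
  S.tol = as<double>(numerics["tol"]);
  S.max_cycles = as<int>(numerics["max_cycles"]);
  int fixed_cycles = as<int>(numerics["fixed_cycles"]);
  if (fixed_cycles > 0) S.max_cycles = fixed_cycles;
  S.total_pressure = as<bool>(numerics["total_pressure"]);
  S.inflow = as<NumericVector>(numerics["inflow"]);
  S.root = as<int>(numerics["root"]);
  double p_init = as<double>(numerics["p_init"]);
  if (S.inflow.size() != S.nsteps + 1)
    stop("inflow vector must have nsteps+1 samples");

  int nv = vessels.size();
  S.V.resize(nv);
  for (int i = 0; i < nv; i++) {
    List vl = vessels[i];
    Vessel& v = S.V[i];
    v.N = as<int>(vl["N"]);
    v.dx = as<double>(vl["dx"]);
    v.dr0dx = as<double>(vl["dr0dx"]);
    v.f = as<std::vector<double>>(vl["f"]);
    v.dfdr = as<std::vector<double>>(vl["dfdr"]);
    v.r0 = as<std::vector<double>>(vl["r0"]);
    v.A0 = as<std::vector<double>>(vl["A0"]);
    v.fh = as<std::vector<double>>(vl["fh"]);
    v.dfdrh = as<std::vector<double>>(vl["dfdrh"]);
    v.r0h = as<std::vector<double>>(vl["r0h"]);
    v.A0h = as<std::vector<double>>(vl["A0h"]);
    v.d1 = as<int>(vl["d1"]);
    v.d2 = as<int>(vl["d2"]);
    v.terminal = (v.d1 < 0);
    v.sqA0.resize(v.N); v.c0n.resize(v.N);
    for (int j = 0; j < v.N; j++) {
      v.sqA0[j] = std::sqrt(v.A0[j]);
      v.c0n[j] = std::sqrt(v.f[j] / (2.0 * S.rho));
    }
    v.sqA0h.resize(v.N - 1);
    for (int j = 0; j < v.N - 1; j++) v.sqA0h[j] = std::sqrt(v.A0h[j]);
    if (v.terminal) {
      NumericVector w = vl["wk"];
      v.wk.R1 = w[0]; v.wk.R2 = w[1]; v.wk.C = w[2]; v.wk.pout = w[3];
      v.wk.pc = p_init;
      if (v.wk.pc < v.wk.pout) v.wk.pc = v.wk.pout;
    }
    if (vl.containsElementNamed("fist") && !Rf_isNull(vl["fist"])) {
      NumericVector fi = vl["fist"];
      v.fist.active = true;
      v.fist.Rf = fi[0]; v.fist.R1v = fi[1]; v.fist.R2v = fi[2];
      v.fist.Cv = fi[3]; v.fist.poutv = fi[4];
      v.fist.pc = v.fist.poutv;
    }
    if (!v.terminal && v.d2 < 0 && !v.fist.active)
      stop("vessel with a single daughter must carry a fistula branch");
    // initial state: uniform pressure p_init, zero flow
    v.A.resize(v.N); v.Q.assign(v.N, 0.0);
    v.Anew.resize(v.N); v.Qnew.resize(v.N);
    v.Ah.resize(v.N - 1); v.Qh.resize(v.N - 1);
    for (int j = 0; j < v.N; j++) {
      double s = 1.0 - (p_init - S.pref) / v.f[j];
      if (s <= 0) stop("initial pressure unreachable by tube law");
      v.A[j] = v.A0[j] / (s * s);
    }
  }

  // output buffers
  int nrow = S.n_out + 1;
  std::vector<NumericMatrix> Pm(nv), Qm(nv), Am(nv);
  for (int i = 0; i < nv; i++) {
    Pm[i] = NumericMatrix(nrow, S.V[i].N);
    Qm[i] = NumericMatrix(nrow, S.V[i].N);
    Am[i] = NumericMatrix(nrow, S.V[i].N);
  }
  NumericMatrix fist_flow(nrow, 1);
  std::vector<int> sample_at(nrow);
  for (int j = 0; j <= S.n_out; j++)
    sample_at[j] = (int)std::lround((double)j * S.nsteps / S.n_out);

  std::vector<double> root_prev(nrow, NA_REAL), root_cur(nrow);
  std::vector<double> resid_trace;
  bool converged = false;
  int cycles = 0;
  double inflow_int = 0, outflow_int = 0, vol0 = 0, vol1 = 0;

  auto record = [&](int row) {
    for (int i = 0; i < nv; i++) {
      Vessel& v = S.V[i];
      Endpt e;
      for (int j = 0; j < v.N; j++) {
        e.f = v.f[j]; e.sqA0 = v.sqA0[j];
        Pm[i](row, j) = S.pref + v.f[j] * (1.0 - v.sqA0[j] / std::sqrt(v.A[j]));
        Qm[i](row, j) = v.Q[j];
        Am[i](row, j) = v.A[j];
      }
      if (v.fist.active) {
        // instantaneous fistula flow from current pressure and state
        double p = Pm[i](row, v.N - 1);
        double alpha = 1.0 / (1.0 + S.dt / (v.fist.R2v * v.fist.Cv));
        double denom = v.fist.Rf + v.fist.R1v + alpha * S.dt / v.fist.Cv;
        fist_flow(row, 0) = (p - alpha * v.fist.pc -
          alpha * S.dt * v.fist.poutv / (v.fist.R2v * v.fist.Cv)) / denom;
      }
    }
    root_cur[row] = Pm[S.root](row, 0);
  };

  for (int cyc = 0; cyc < S.max_cycles && !converged; cyc++) {
    cycles = cyc + 1;
    int next_sample = 0;
    inflow_int = 0; outflow_int = 0;
    vol0 = S.volume();
    if (sample_at[0] == 0) { record(0); next_sample = 1; }
    for (int k = 0; k < S.nsteps; k++) {
      // trapezoid accumulation of boundary flows over the step
      double qin0 = S.V[S.root].Q[0];
      double qout0 = 0;
      for (int i = 0; i < nv; i++) {
        if (S.V[i].terminal) qout0 += S.V[i].Q[S.V[i].N - 1];
        if (S.V[i].fist.active) {
          double p = S.pref + S.V[i].f[S.V[i].N - 1] *
            (1.0 - S.V[i].sqA0[S.V[i].N - 1] /
             std::sqrt(S.V[i].A[S.V[i].N - 1]));
          double alpha = 1.0 / (1.0 + S.dt / (S.V[i].fist.R2v * S.V[i].fist.Cv));
          double denom = S.V[i].fist.Rf + S.V[i].fist.R1v +
            alpha * S.dt / S.V[i].fist.Cv;
          qout0 += (p - alpha * S.V[i].fist.pc - alpha * S.dt *
                    S.V[i].fist.poutv /
                    (S.V[i].fist.R2v * S.V[i].fist.Cv)) / denom;
        }
      }
      S.step(k);
      double qin1 = S.V[S.root].Q[0];
      double qout1 = 0;
      for (int i = 0; i < nv; i++)
        if (S.V[i].terminal) qout1 += S.V[i].Q[S.V[i].N - 1];
      for (int i = 0; i < nv; i++) {
        if (S.V[i].fist.active) {
          double p = S.pref + S.V[i].f[S.V[i].N - 1] *
            (1.0 - S.V[i].sqA0[S.V[i].N - 1] /
             std::sqrt(S.V[i].A[S.V[i].N - 1]));
          double alpha = 1.0 / (1.0 + S.dt / (S.V[i].fist.R2v * S.V[i].fist.Cv));
          double denom = S.V[i].fist.Rf + S.V[i].fist.R1v +
            alpha * S.dt / S.V[i].fist.Cv;
          qout1 += (p - alpha * S.V[i].fist.pc - alpha * S.dt *
                    S.V[i].fist.poutv /
                    (S.V[i].fist.R2v * S.V[i].fist.Cv)) / denom;
        }
      }
      inflow_int += 0.5 * (qin0 + qin1) * S.dt;
      outflow_int += 0.5 * (qout0 + qout1) * S.dt;
      if (next_sample < nrow && (k + 1) == sample_at[next_sample]) {
        record(next_sample);
        next_sample++;
      }
    }
    vol1 = S.volume();
    if (cyc > 0) {
      double resid = 0;
      for (int j = 0; j < nrow; j++)
        resid = std::max(resid, std::fabs(root_cur[j] - root_prev[j]));
      resid_trace.push_back(resid);
      if (fixed_cycles > 0) {
        if (cycles == fixed_cycles) converged = (resid < S.tol);
      } else if (resid < S.tol) converged = true;
    }
    root_prev = root_cur;
    Rcpp::checkUserInterrupt();
  }

  List out_v(nv);
  for (int i = 0; i < nv; i++)
    out_v[i] = List::create(_["p"] = Pm[i], _["q"] = Qm[i], _["A"] = Am[i]);

  return List::create(
    _["fields"] = out_v,
    _["cycles"] = cycles,
    _["converged"] = converged,
    _["residuals"] = resid_trace,
    _["inflow_volume"] = inflow_int,
    _["outflow_volume"] = outflow_int,
    _["volume_change"] = vol1 - vol0,
    _["fistula_flow"] = fist_flow
  );
}
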