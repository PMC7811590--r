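// Two-step (Richtmyer) Lax-Wendroff solver for the 1D blood-flow system
//
//   A_t + q_x = 0
//   q_t + (q^2/A + B(A))_x = -2 sqrt(pi) mu q / (rho delta sqrt(A))
//
// on a bifurcating vessel network, closed by an algebraic wall law
// (linear or tangent-nonlinear), flow conservation + pressure continuity at
// junctions, a prescribed periodic inflow at the root and three-element
// Windkessel (RCR) outlets discretized by the trapezoidal rule. Boundary
// nodes are updated from the outgoing characteristics (predictor-corrected
// foot point, friction-corrected Riemann invariant) with damped Newton
// iteration. Everything here is in cgs units; pressure conversion to mmHg
// happens in the R wrapper.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

namespace {

struct Wall {
  int kind;        // 0 linear, 1 nonlinear
  double gamma;    // nonlinear only
  double chi, A0, rho;
  double Bcoef, A0_32, c0lin;   // precomputed (linear wall fast path)

  void precompute() {
    A0_32 = A0 * std::sqrt(A0);
    Bcoef = 4.0 * chi / (9.0 * rho * std::sqrt(A0));
    c0lin = std::sqrt(2.0 * chi / (3.0 * rho));
  }

  double ptilde(double A) const {
    double r = A / A0;
    if (kind == 0) return (4.0 / 3.0) * chi * (std::sqrt(r) - 1.0);
    double arg = (M_PI / gamma) * (r - 1.0);
    if (std::fabs(arg) >= M_PI_2 * 0.999999)
      throw std::runtime_error("wall-law blow-up (tangent argument)");
    return chi * std::tan(arg);
  }
  double dpda(double A) const {
    if (kind == 0) return (2.0 / 3.0) * chi / std::sqrt(A * A0);
    double arg = (M_PI / gamma) * (A / A0 - 1.0);
    double c = std::cos(arg);
    return chi * (M_PI / (gamma * A0)) / (c * c);
  }
  // momentum "pressure flux": B(A) with dB/dA = (A/rho) dptilde/dA
  double Bflux(double A) const {
    double r = A / A0;
    if (kind == 0)
      return Bcoef * (A * std::sqrt(A) - A0_32);
    double u = r - 1.0, a = M_PI / gamma;
    double arg = a * u;
    if (std::fabs(arg) >= M_PI_2 * 0.999999)
      throw std::runtime_error("wall-law blow-up (tangent argument)");
    return (chi * A0 / rho) *
           (r * std::tan(arg) + (gamma / M_PI) * std::log(std::cos(arg)));
  }
  double cspeed(double A) const {
    if (kind == 0) return c0lin * std::pow(A / A0, 0.25);
    return std::sqrt(std::max(1e-30, (A / rho) * dpda(A)));
  }
  // Riemann-invariant integral phi(A) = int_{A0}^{A} c(a)/a da
  double phi(double A) const {
    if (kind == 0) return 4.0 * (cspeed(A) - c0lin);
    // 8-point Gauss-Legendre on [A0, A]
    static const double gx[4] = {0.1834346424956498, 0.5255324099163290,
                                 0.7966664774136267, 0.9602898564975363};
    static const double gw[4] = {0.3626837833783620, 0.3137066458778873,
                                 0.2223810344533745, 0.1012285362903763};
    double h = 0.5 * (A - A0), mid = 0.5 * (A + A0), s = 0.0;
    for (int k = 0; k < 4; ++k) {
      double a1 = mid + h * gx[k], a2 = mid - h * gx[k];
      s += gw[k] * (cspeed(a1) / a1 + cspeed(a2) / a2);
    }
    return h * s;
  }
};

struct Vessel {
  int n;              // nodes
  double dx, L;
  Wall wall;
  std::vector<double> A, q;        // state at time n
  std::vector<double> Ah, qh;      // half-step values at i+1/2
  std::vector<double> An, qn;      // state at time n+1
  // terminal bookkeeping
  bool terminal;
  double R1, R2, C;
};

struct Net {
  std::vector<Vessel> ves;
  IntegerMatrix junc;   // rows: parent, d1, d2 (0-based)
  int root;
  double rho, mu, delta;
};

inline double friction(const Net &net, const Vessel &v, double A, double q) {
  return -2.0 * std::sqrt(M_PI) * net.mu * q /
         (net.rho * net.delta * std::sqrt(A));
}

// linear interpolation of (A, q) a distance xi upstream of node `anchor`
// (dir = -1) or downstream of it (dir = +1)
inline void interp_state(const Vessel &v, int anchor, int dir, double xi,
                         double &Ai, double &qi) {
  double frac = xi / v.dx;
  if (frac < 0.0) frac = 0.0;
  if (frac > 1.0) frac = 1.0;
  int other = anchor + dir;
  Ai = (1.0 - frac) * v.A[anchor] + frac * v.A[other];
  qi = (1.0 - frac) * v.q[anchor] + frac * v.q[other];
}

// friction-corrected outgoing Riemann invariant reaching the distal end
// (node n-1, lambda+ = u + c): W+ = u + phi(A)
double invariant_plus(const Net &net, const Vessel &v, double dt) {
  int M = v.n - 1;
  double u = v.q[M] / v.A[M], c = v.wall.cspeed(v.A[M]);
  double xi = (u + c) * dt, Ai, qi;
  interp_state(v, M, -1, xi, Ai, qi);
  double uf = qi / Ai, cf = v.wall.cspeed(Ai);
  xi = 0.5 * ((u + c) + (uf + cf)) * dt;          // corrected foot point
  interp_state(v, M, -1, xi, Ai, qi);
  return qi / Ai + v.wall.phi(Ai) + dt * friction(net, v, Ai, qi) / Ai;
}

// outgoing invariant reaching the proximal end (node 0, lambda- = u - c):
// W- = u - phi(A)
double invariant_minus(const Net &net, const Vessel &v, double dt) {
  double u = v.q[0] / v.A[0], c = v.wall.cspeed(v.A[0]);
  double xi = (c - u) * dt, Ai, qi;
  interp_state(v, 0, +1, xi, Ai, qi);
  double uf = qi / Ai, cf = v.wall.cspeed(Ai);
  xi = 0.5 * ((c - u) + (cf - uf)) * dt;
  interp_state(v, 0, +1, xi, Ai, qi);
  return qi / Ai - v.wall.phi(Ai) + dt * friction(net, v, Ai, qi) / Ai;
}

// 6x6 dense linear solve (Gaussian elimination, partial pivoting)
bool solve_dense(int n, std::vector<double> &J, std::vector<double> &b) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(J[r * n + col]) > std::fabs(J[piv * n + col])) piv = r;
    if (std::fabs(J[piv * n + col]) < 1e-300) return false;
    if (piv != col) {
      for (int k = 0; k < n; ++k) std::swap(J[col * n + k], J[piv * n + k]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      double f = J[r * n + col] / J[col * n + col];
      for (int k = col; k < n; ++k) J[r * n + k] -= f * J[col * n + k];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < n; ++k) s -= J[r * n + k] * b[k];
    b[r] = s / J[r * n + r];
  }
  return true;
}

void newton_fail(const std::string &where, double t) {
  throw std::runtime_error("Newton iteration failed to converge at " + where +
                           ", t = " + std::to_string(t) + " s");
}

} // namespace

// [[Rcpp::export(name = ".lw_simulate")]]
List lw_simulate(NumericVector L, NumericVector A0, NumericVector chi,
                 int wall_kind, double gamma,
                 IntegerMatrix junctions, int root,
                 IntegerVector terminal_idx,
                 NumericVector R1, NumericVector R2, NumericVector Cap,
                 NumericVector inflow_t, NumericVector inflow_q,
                 double rho, double mu, double delta, double period,
                 double dx, double dt, int n_cycles, double conv_tol,
                 int n_out) {
  const int nv = L.size();
  Net net;
  net.junc = junctions;
  net.root = root;
  net.rho = rho; net.mu = mu; net.delta = delta;
  net.ves.resize(nv);

  for (int v = 0; v < nv; ++v) {
    Vessel &V = net.ves[v];
    int M = std::max(2, (int)std::ceil(L[v] / dx));
    V.n = M + 1;
    V.L = L[v];
    V.dx = L[v] / M;
    V.wall.kind = wall_kind;
    V.wall.gamma = gamma;
    V.wall.chi = chi[v];
    V.wall.A0 = A0[v];
    V.wall.rho = rho;
    V.wall.precompute();
    V.A.assign(V.n, A0[v]);
    V.q.assign(V.n, 0.0);
    V.Ah.assign(V.n - 1, A0[v]);
    V.qh.assign(V.n - 1, 0.0);
    V.An = V.A; V.qn = V.q;
    V.terminal = false;
  }
  for (int k = 0; k < terminal_idx.size(); ++k) {
    Vessel &V = net.ves[terminal_idx[k]];
    V.terminal = true;
    V.R1 = R1[k]; V.R2 = R2[k]; V.C = Cap[k];
  }

  // periodic linear interpolation of the inflow waveform
  const int ni = inflow_t.size();
  auto qin = [&](double t) -> double {
    double tm = t - std::floor(t / period) * period;
    // inflow_t assumed increasing within [0, period]
    int lo = 0, hi = ni - 1;
    if (tm <= inflow_t[0] || tm >= inflow_t[ni - 1]) {
      double t0 = inflow_t[ni - 1], t1 = inflow_t[0] + period;
      double dtm = tm - t0 + period;
      dtm -= std::floor(dtm / period) * period;
      double w = (t1 > t0) ? dtm / (t1 - t0) : 0.0;
      return (1.0 - w) * inflow_q[ni - 1] + w * inflow_q[0];
    }
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (inflow_t[mid] <= tm) lo = mid; else hi = mid;
    }
    double w = (tm - inflow_t[lo]) / (inflow_t[hi] - inflow_t[lo]);
    return (1.0 - w) * inflow_q[lo] + w * inflow_q[hi];
  };

  const int steps = std::max(16, (int)std::lround(period / dt));
  const double dtt = period / steps;
  if (n_out > steps) n_out = steps;
  // which step indices to record (n_out + 1 samples incl. both cycle ends)
  std::vector<int> rec_step(n_out + 1);
  for (int j = 0; j <= n_out; ++j)
    rec_step[j] = (int)std::lround((double)j * steps / n_out);

  // output buffers: per vessel, nodes x (n_out+1); keep previous cycle too
  std::vector<NumericMatrix> outA(nv), outQ(nv);
  std::vector<std::vector<double>> prevP(nv), curP(nv);
  for (int v = 0; v < nv; ++v) {
    outA[v] = NumericMatrix(net.ves[v].n, n_out + 1);
    outQ[v] = NumericMatrix(net.ves[v].n, n_out + 1);
    prevP[v].assign(net.ves[v].n * (n_out + 1), 0.0);
    curP[v].assign(net.ves[v].n * (n_out + 1), 0.0);
  }

  double courant_max = 0.0;
  int cycles_run = 0;
  bool converged = false;
  const double newton_tol = 1e-10;

  auto record = [&](int slot) {
    for (int v = 0; v < nv; ++v) {
      Vessel &V = net.ves[v];
      for (int i = 0; i < V.n; ++i) {
        outA[v](i, slot) = V.A[i];
        outQ[v](i, slot) = V.q[i];
        curP[v][i * (n_out + 1) + slot] = V.wall.ptilde(V.A[i]);
      }
    }
  };

  try {
  for (int cyc = 0; cyc < n_cycles && !converged; ++cyc) {
    std::swap(prevP, curP);
    int rec_ptr = 0;
    for (int s = 0; s < steps; ++s) {
      double t = cyc * period + s * dtt;
      while (rec_ptr <= n_out && rec_step[rec_ptr] == s) record(rec_ptr++);

      // --- CFL monitor over current state ---
      for (int v = 0; v < nv; ++v) {
        Vessel &V = net.ves[v];
        for (int i = 0; i < V.n; ++i) {
          double lam = std::fabs(V.q[i] / V.A[i]) + V.wall.cspeed(V.A[i]);
          double cn = lam * dtt / V.dx;
          if (cn > courant_max) courant_max = cn;
        }
      }
      if (courant_max > 1.0)
        throw std::runtime_error(
            "CFL condition violated (Courant number " +
            std::to_string(courant_max) + " > 1) at t = " + std::to_string(t));

      // --- Richtmyer half step + interior full step ---
      for (int v = 0; v < nv; ++v) {
        Vessel &V = net.ves[v];
        int M = V.n - 1;
        for (int i = 0; i < M; ++i) {
          double Al = V.A[i], Ar = V.A[i + 1];
          double ql = V.q[i], qr = V.q[i + 1];
          double F1l = ql, F1r = qr;
          double F2l = ql * ql / Al + V.wall.Bflux(Al);
          double F2r = qr * qr / Ar + V.wall.Bflux(Ar);
          double Sl = friction(net, V, Al, ql);
          double Sr = friction(net, V, Ar, qr);
          V.Ah[i] = 0.5 * (Al + Ar) - 0.5 * dtt / V.dx * (F1r - F1l);
          V.qh[i] = 0.5 * (ql + qr) - 0.5 * dtt / V.dx * (F2r - F2l) +
                    0.25 * dtt * (Sl + Sr);
          if (V.Ah[i] <= 0.0)
            throw std::runtime_error("negative area at half step, t = " +
                                     std::to_string(t));
        }
        for (int i = 1; i < M; ++i) {
          double F1l = V.qh[i - 1], F1r = V.qh[i];
          double F2l = V.qh[i - 1] * V.qh[i - 1] / V.Ah[i - 1] +
                       V.wall.Bflux(V.Ah[i - 1]);
          double F2r = V.qh[i] * V.qh[i] / V.Ah[i] + V.wall.Bflux(V.Ah[i]);
          double Sl = friction(net, V, V.Ah[i - 1], V.qh[i - 1]);
          double Sr = friction(net, V, V.Ah[i], V.qh[i]);
          V.An[i] = V.A[i] - dtt / V.dx * (F1r - F1l);
          V.qn[i] = V.q[i] - dtt / V.dx * (F2r - F2l) + 0.5 * dtt * (Sl + Sr);
          if (V.An[i] <= 0.0)
            throw std::runtime_error("negative area in interior, t = " +
                                     std::to_string(t));
        }
      }

      double tn1 = t + dtt;

      // --- root inlet: prescribed q, A from the outgoing lambda- ---
      {
        Vessel &V = net.ves[net.root];
        double Wm = invariant_minus(net, V, dtt);
        double qb = qin(tn1);
        double Ab = V.A[0];
        double scale = V.wall.cspeed(V.wall.A0);
        bool ok = false;
        for (int it = 0; it < 30; ++it) {
          double g = (qb / Ab - V.wall.phi(Ab) - Wm) / scale;
          if (std::fabs(g) < newton_tol) { ok = true; break; }
          double dg = (-qb / (Ab * Ab) - V.wall.cspeed(Ab) / Ab) / scale;
          double step = -g / dg, lam = 1.0;
          for (int h = 0; h < 12; ++h) {
            double Atry = Ab + lam * step;
            if (Atry > 0.1 * V.wall.A0) {
              double gt = (qb / Atry - V.wall.phi(Atry) - Wm) / scale;
              if (std::fabs(gt) <= std::fabs(g)) { Ab = Atry; break; }
            }
            lam *= 0.5;
            if (h == 11) Ab = std::max(0.1 * V.wall.A0, Ab + lam * step);
          }
        }
        if (!ok) newton_fail("root inlet", tn1);
        V.An[0] = Ab; V.qn[0] = qb;
      }

      // --- junctions: parent outlet + two daughter inlets ---
      for (int j = 0; j < junctions.nrow(); ++j) {
        Vessel &P = net.ves[junctions(j, 0)];
        Vessel &D1 = net.ves[junctions(j, 1)];
        Vessel &D2 = net.ves[junctions(j, 2)];
        int Mp = P.n - 1;
        double Wp = invariant_plus(net, P, dtt);
        double W1 = invariant_minus(net, D1, dtt);
        double W2 = invariant_minus(net, D2, dtt);
        // unknowns x = (Ap, qp, A1, q1, A2, q2)
        double x[6] = {P.A[Mp], P.q[Mp], D1.A[0], D1.q[0], D2.A[0], D2.q[0]};
        double c0p = P.wall.cspeed(P.wall.A0);
        double pscale = rho * c0p * c0p, qscale = P.wall.A0 * c0p;
        auto resid = [&](const double *x, double *g) {
          g[0] = (x[1] / x[0] + P.wall.phi(x[0]) - Wp) / c0p;
          g[1] = (x[3] / x[2] - D1.wall.phi(x[2]) - W1) / c0p;
          g[2] = (x[5] / x[4] - D2.wall.phi(x[4]) - W2) / c0p;
          g[3] = (P.wall.ptilde(x[0]) - D1.wall.ptilde(x[2])) / pscale;
          g[4] = (P.wall.ptilde(x[0]) - D2.wall.ptilde(x[4])) / pscale;
          g[5] = (x[1] - x[3] - x[5]) / qscale;
        };
        double g[6];
        resid(x, g);
        double gn = 0; for (int k = 0; k < 6; ++k) gn += g[k] * g[k];
        bool ok = std::sqrt(gn) < newton_tol;
        for (int it = 0; it < 30 && !ok; ++it) {
          std::vector<double> J(36, 0.0), b(6);
          // row 0: parent characteristic
          J[0 * 6 + 0] = (-x[1] / (x[0] * x[0]) +
                          P.wall.cspeed(x[0]) / x[0]) / c0p;
          J[0 * 6 + 1] = (1.0 / x[0]) / c0p;
          // rows 1-2: daughter characteristics
          J[1 * 6 + 2] = (-x[3] / (x[2] * x[2]) -
                          D1.wall.cspeed(x[2]) / x[2]) / c0p;
          J[1 * 6 + 3] = (1.0 / x[2]) / c0p;
          J[2 * 6 + 4] = (-x[5] / (x[4] * x[4]) -
                          D2.wall.cspeed(x[4]) / x[4]) / c0p;
          J[2 * 6 + 5] = (1.0 / x[4]) / c0p;
          // rows 3-4: pressure continuity
          J[3 * 6 + 0] = P.wall.dpda(x[0]) / pscale;
          J[3 * 6 + 2] = -D1.wall.dpda(x[2]) / pscale;
          J[4 * 6 + 0] = P.wall.dpda(x[0]) / pscale;
          J[4 * 6 + 4] = -D2.wall.dpda(x[4]) / pscale;
          // row 5: flow conservation
          J[5 * 6 + 1] = 1.0 / qscale;
          J[5 * 6 + 3] = -1.0 / qscale;
          J[5 * 6 + 5] = -1.0 / qscale;
          for (int k = 0; k < 6; ++k) b[k] = -g[k];
          if (!solve_dense(6, J, b)) newton_fail("junction", tn1);
          double lam = 1.0;
          for (int h = 0; h < 12; ++h) {
            double xt[6], gt[6];
            bool pos = true;
            for (int k = 0; k < 6; ++k) xt[k] = x[k] + lam * b[k];
            if (xt[0] <= 0.1 * P.wall.A0 || xt[2] <= 0.1 * D1.wall.A0 ||
                xt[4] <= 0.1 * D2.wall.A0) pos = false;
            if (pos) {
              resid(xt, gt);
              double gtn = 0; for (int k = 0; k < 6; ++k) gtn += gt[k] * gt[k];
              if (gtn <= gn || h == 11) {
                for (int k = 0; k < 6; ++k) { x[k] = xt[k]; g[k] = gt[k]; }
                gn = gtn;
                break;
              }
            }
            lam *= 0.5;
          }
          ok = std::sqrt(gn) < newton_tol;
        }
        if (!ok) newton_fail("junction", tn1);
        P.An[Mp] = x[0]; P.qn[Mp] = x[1];
        D1.An[0] = x[2]; D1.qn[0] = x[3];
        D2.An[0] = x[4]; D2.qn[0] = x[5];
      }

      // --- terminal outlets: characteristic + trapezoidal Windkessel ---
      for (int v = 0; v < nv; ++v) {
        Vessel &V = net.ves[v];
        if (!V.terminal) continue;
        int M = V.n - 1;
        double Wp = invariant_plus(net, V, dtt);
        double pn = V.wall.ptilde(V.A[M]), qn_old = V.q[M];
        double rc = V.R2 * V.C;
        double fn = ((V.R1 + V.R2) * qn_old - pn) / rc;
        double A = V.A[M], q = V.q[M];
        double c0 = V.wall.cspeed(V.wall.A0);
        double pscale = rho * c0 * c0;
        auto resid = [&](double A, double q, double *g) {
          double p = V.wall.ptilde(A);
          double f1 = ((V.R1 + V.R2) * q - p) / rc;
          g[0] = (q / A + V.wall.phi(A) - Wp) / c0;
          g[1] = ((p - pn) - V.R1 * (q - qn_old) -
                  0.5 * dtt * (f1 + fn)) / pscale;
        };
        double g[2];
        resid(A, q, g);
        double gn = g[0] * g[0] + g[1] * g[1];
        bool ok = std::sqrt(gn) < newton_tol;
        for (int it = 0; it < 30 && !ok; ++it) {
          double dpdA = V.wall.dpda(A);
          double J00 = (-q / (A * A) + V.wall.cspeed(A) / A) / c0;
          double J01 = (1.0 / A) / c0;
          double J10 = (dpdA + 0.5 * dtt * dpdA / rc) / pscale;
          double J11 = (-V.R1 - 0.5 * dtt * (V.R1 + V.R2) / rc) / pscale;
          double det = J00 * J11 - J01 * J10;
          if (std::fabs(det) < 1e-300) newton_fail("Windkessel outlet", tn1);
          double dA = (-g[0] * J11 + g[1] * J01) / det;
          double dq = (-J00 * g[1] + J10 * g[0]) / det;
          double lam = 1.0;
          for (int h = 0; h < 12; ++h) {
            double At = A + lam * dA, qt = q + lam * dq, gt[2];
            if (At > 0.1 * V.wall.A0) {
              resid(At, qt, gt);
              double gtn = gt[0] * gt[0] + gt[1] * gt[1];
              if (gtn <= gn || h == 11) {
                A = At; q = qt; g[0] = gt[0]; g[1] = gt[1]; gn = gtn;
                break;
              }
            }
            lam *= 0.5;
          }
          ok = std::sqrt(gn) < newton_tol;
        }
        if (!ok) newton_fail("Windkessel outlet", tn1);
        V.An[M] = A; V.qn[M] = q;
      }

      for (int v = 0; v < nv; ++v) {
        net.ves[v].A = net.ves[v].An;
        net.ves[v].q = net.ves[v].qn;
      }
    }
    // final sample of the cycle (state at t = (cyc+1) * period)
    record(n_out);
    cycles_run = cyc + 1;

    if (cyc > 0) {
      double dmax = 0.0, amp = 0.0;
      for (int v = 0; v < nv; ++v) {
        double pmin = 1e300, pmax = -1e300;
        for (size_t k = 0; k < curP[v].size(); ++k) {
          dmax = std::max(dmax, std::fabs(curP[v][k] - prevP[v][k]));
          pmin = std::min(pmin, curP[v][k]);
          pmax = std::max(pmax, curP[v][k]);
        }
        amp = std::max(amp, pmax - pmin);
      }
      if (amp > 0 && dmax / amp < conv_tol) converged = true;
    }
  }
  } catch (std::exception &e) {
    stop(std::string("haemodynamic solver: ") + e.what());
  }

  List Aout(nv), Qout(nv), Pout(nv), xgrid(nv);
  for (int v = 0; v < nv; ++v) {
    Vessel &V = net.ves[v];
    NumericMatrix P(V.n, n_out + 1);
    for (int i = 0; i < V.n; ++i)
      for (int j = 0; j <= n_out; ++j)
        P(i, j) = V.wall.ptilde(outA[v](i, j));
    Aout[v] = outA[v];
    Qout[v] = outQ[v];
    Pout[v] = P;
    NumericVector xv(V.n);
    for (int i = 0; i < V.n; ++i) xv[i] = i * V.dx;
    xgrid[v] = xv;
  }
  NumericVector tout(n_out + 1);
  for (int j = 0; j <= n_out; ++j) tout[j] = rec_step[j] * dtt;

  return List::create(_["A"] = Aout, _["q"] = Qout, _["p_cgs"] = Pout,
                      _["x"] = xgrid, _["t"] = tout,
                      _["dt"] = dtt, _["cycles"] = cycles_run,
                      _["converged"] = converged,
                      _["courant_max"] = courant_max);
}
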