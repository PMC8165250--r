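// Shared planar rigid-body machinery of the three-joint, five-link
// standing model.
//
// The chain is parametrised through per-body centre-of-mass "term lists":
// every moving body's CoM is a sum of terms  a_ij * (sin phi_j, cos phi_j)
// over absolute link angles phi = phi0 + A q (A constant).  That
// representation yields closed-form CoM Jacobians, from which the mass
// matrix M(q) = sum_i m_i J_i' J_i + I_i A_i' A_i and the bias vector
// (Coriolis/centrifugal + gravity, i.e. inverse dynamics at qdd = 0)
// follow without any symbolic algebra.  Bodies: 1 lower body, 2 upper
// body, 3 lumped arms (hanging from the shoulder).  The foot is a welded
// base and only enters whole-body CoM bookkeeping.

#ifndef ARMBALANCE_MODEL_H
#define ARMBALANCE_MODEL_H

#include <Rcpp.h>
#include <cmath>
#include <cstring>

namespace armbalance {

constexpr int NB = 3;     // moving bodies
constexpr int NMAX = 3;   // max dof
constexpr int NSMAX = 6;  // max state dimension

struct Model {
  int mode;               // 0 active, 1 passive, 2 fixed
  int n;                  // dof (3 active/passive, 2 fixed)
  int nu;                 // actuated joints (3 active, 2 passive/fixed)
  double g;
  double mb[NB];          // body masses
  double Ib[NB];          // body rotational inertias about own CoM
  double a[NB][NB];       // CoM term coefficients on angle phi_j
  double A[NB][NMAX];     // dphi/dq (NB x n)
  double phi0[NB];        // constant angle offsets: phi = phi0 + A q
  double m_tot, m_foot, foot_cx, foot_cz, h0, com_x_off;
};

inline Model parse_model(const Rcpp::List& L) {
  using Rcpp::as;
  Model M;
  M.mode = as<int>(L["mode"]);
  M.n = as<int>(L["n"]);
  M.nu = as<int>(L["nu"]);
  M.g = as<double>(L["g"]);
  Rcpp::NumericVector mb = L["mb"], Ib = L["Ib"], ph = L["phi0"];
  Rcpp::NumericMatrix ac = L["acoef"], Am = L["Amat"];
  for (int i = 0; i < NB; ++i) {
    M.mb[i] = mb[i];
    M.Ib[i] = Ib[i];
    M.phi0[i] = ph[i];
    for (int j = 0; j < NB; ++j) M.a[i][j] = ac(i, j);
    for (int k = 0; k < M.n; ++k) M.A[i][k] = Am(i, k);
  }
  M.m_tot = as<double>(L["m_tot"]);
  M.m_foot = as<double>(L["m_foot"]);
  M.foot_cx = as<double>(L["foot_cx"]);
  M.foot_cz = as<double>(L["foot_cz"]);
  M.h0 = as<double>(L["h0"]);
  M.com_x_off = as<double>(L["com_x_off"]);
  return M;
}

inline void angles(const Model& M, const double* q, double* phi,
                   double* sp, double* cp) {
  for (int i = 0; i < NB; ++i) {
    double v = M.phi0[i];
    for (int k = 0; k < M.n; ++k) v += M.A[i][k] * q[k];
    phi[i] = v;
    sp[i] = std::sin(v);
    cp[i] = std::cos(v);
  }
}

// CoM Jacobian of body i: rows (x, z), columns q.
inline void body_jac(const Model& M, int i, const double* sp,
                     const double* cp, double Jx[NMAX], double Jz[NMAX]) {
  for (int k = 0; k < M.n; ++k) { Jx[k] = 0.0; Jz[k] = 0.0; }
  for (int j = 0; j < NB; ++j) {
    double aij = M.a[i][j];
    if (aij == 0.0) continue;
    for (int k = 0; k < M.n; ++k) {
      double Ajk = M.A[j][k];
      if (Ajk == 0.0) continue;
      Jx[k] += aij * cp[j] * Ajk;
      Jz[k] -= aij * sp[j] * Ajk;
    }
  }
}

inline void mass_matrix(const Model& M, const double* q,
                        double Mq[NMAX][NMAX]) {
  double phi[NB], sp[NB], cp[NB], Jx[NMAX], Jz[NMAX];
  angles(M, q, phi, sp, cp);
  for (int r = 0; r < M.n; ++r)
    for (int c = 0; c < M.n; ++c) Mq[r][c] = 0.0;
  for (int i = 0; i < NB; ++i) {
    body_jac(M, i, sp, cp, Jx, Jz);
    for (int r = 0; r < M.n; ++r)
      for (int c = 0; c < M.n; ++c)
        Mq[r][c] += M.mb[i] * (Jx[r] * Jx[c] + Jz[r] * Jz[c]) +
                    M.Ib[i] * M.A[i][r] * M.A[i][c];
  }
}

// Coriolis/centrifugal + gravity generalized forces (inverse dynamics with
// qdd = 0):  bias_k = sum_i m_i J_i[:,k] . (a0_i + (0, g)), where a0_i is
// the body CoM acceleration at qdd = 0.
inline void bias_vector(const Model& M, const double* q, const double* qd,
                        double* bias) {
  double phi[NB], sp[NB], cp[NB], Jx[NMAX], Jz[NMAX];
  angles(M, q, phi, sp, cp);
  double phid[NB];
  for (int i = 0; i < NB; ++i) {
    double v = 0.0;
    for (int k = 0; k < M.n; ++k) v += M.A[i][k] * qd[k];
    phid[i] = v;
  }
  for (int k = 0; k < M.n; ++k) bias[k] = 0.0;
  for (int i = 0; i < NB; ++i) {
    double ax = 0.0, az = M.g;  // gravity enters as +g on the z row
    for (int j = 0; j < NB; ++j) {
      double aij = M.a[i][j];
      if (aij == 0.0) continue;
      double w2 = phid[j] * phid[j];
      ax -= aij * w2 * sp[j];
      az -= aij * w2 * cp[j];
    }
    body_jac(M, i, sp, cp, Jx, Jz);
    for (int k = 0; k < M.n; ++k)
      bias[k] += M.mb[i] * (Jx[k] * ax + Jz[k] * az);
  }
}

// Generalized force of a horizontal force F applied at the upper-body CoM
// (body index 1): F * d(x_com,upper)/dq.
inline void push_vector(const Model& M, const double* q, double F,
                        double* out) {
  double phi[NB], sp[NB], cp[NB], Jx[NMAX], Jz[NMAX];
  angles(M, q, phi, sp, cp);
  body_jac(M, 1, sp, cp, Jx, Jz);
  for (int k = 0; k < M.n; ++k) out[k] = F * Jx[k];
}

// Solve S x = b for n <= 3 by Gaussian elimination with partial pivoting.
inline bool solve_n(int n, double S[NMAX][NMAX], double* b, double* x) {
  double Aw[NMAX][NMAX + 1];
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < n; ++c) Aw[r][c] = S[r][c];
    Aw[r][n] = b[r];
  }
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(Aw[r][col]) > std::fabs(Aw[piv][col])) piv = r;
    if (std::fabs(Aw[piv][col]) < 1e-14) return false;
    if (piv != col)
      for (int c = col; c <= n; ++c) std::swap(Aw[piv][c], Aw[col][c]);
    for (int r = col + 1; r < n; ++r) {
      double f = Aw[r][col] / Aw[col][col];
      for (int c = col; c <= n; ++c) Aw[r][c] -= f * Aw[col][c];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = Aw[r][n];
    for (int c = r + 1; c < n; ++c) s -= Aw[r][c] * x[c];
    x[r] = s / Aw[r][r];
  }
  return true;
}

// tau has length nu; passive mode pads the (unactuated) arm joint with 0.
inline void full_torque(const Model& M, const double* tau, double* tf) {
  for (int k = 0; k < M.n; ++k) tf[k] = 0.0;
  if (M.mode == 1) { tf[0] = tau[0]; tf[1] = tau[1]; }
  else for (int k = 0; k < M.nu; ++k) tf[k] = tau[k];
}

inline bool qdd_eval(const Model& M, const double* q, const double* qd,
                     const double* tau, double F, double* qdd) {
  double Mq[NMAX][NMAX], bias[NMAX], pv[NMAX], rhs[NMAX], tf[NMAX];
  mass_matrix(M, q, Mq);
  bias_vector(M, q, qd, bias);
  push_vector(M, q, F, pv);
  full_torque(M, tau, tf);
  for (int k = 0; k < M.n; ++k) rhs[k] = tf[k] + pv[k] - bias[k];
  return solve_n(M.n, Mq, rhs, qdd);
}

inline bool state_deriv(const Model& M, const double* x, const double* tau,
                        double F, double* dx) {
  const double* q = x;
  const double* qd = x + M.n;
  for (int k = 0; k < M.n; ++k) dx[k] = qd[k];
  return qdd_eval(M, q, qd, tau, F, dx + M.n);
}

inline bool rk4_step(const Model& M, double* x, const double* tau, double F,
                     double dt) {
  int m = 2 * M.n;
  double k1[NSMAX], k2[NSMAX], k3[NSMAX], k4[NSMAX], xt[NSMAX];
  if (!state_deriv(M, x, tau, F, k1)) return false;
  for (int i = 0; i < m; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  if (!state_deriv(M, xt, tau, F, k2)) return false;
  for (int i = 0; i < m; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  if (!state_deriv(M, xt, tau, F, k3)) return false;
  for (int i = 0; i < m; ++i) xt[i] = x[i] + dt * k3[i];
  if (!state_deriv(M, xt, tau, F, k4)) return false;
  for (int i = 0; i < m; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  return true;
}

}  // namespace armbalance

#endif
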