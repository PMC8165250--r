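// Exported evaluators of the standing-model dynamics (see model.h for the
// underlying chain parametrisation).

#include "model.h"

using namespace Rcpp;
using namespace armbalance;

// [[Rcpp::export]]
NumericMatrix cpp_mass_matrix(List model, NumericVector q) {
  Model M = parse_model(model);
  double Mq[NMAX][NMAX];
  mass_matrix(M, REAL(q), Mq);
  NumericMatrix out(M.n, M.n);
  for (int r = 0; r < M.n; ++r)
    for (int c = 0; c < M.n; ++c) out(r, c) = Mq[r][c];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bias(List model, NumericVector q, NumericVector qd) {
  Model M = parse_model(model);
  double b[NMAX];
  bias_vector(M, REAL(q), REAL(qd), b);
  return NumericVector(b, b + M.n);
}

// [[Rcpp::export]]
NumericVector cpp_push_vec(List model, NumericVector q, double force) {
  Model M = parse_model(model);
  double p[NMAX];
  push_vector(M, REAL(q), force, p);
  return NumericVector(p, p + M.n);
}

// [[Rcpp::export]]
NumericVector cpp_qdd(List model, NumericVector q, NumericVector qd,
                      NumericVector tau, double force) {
  Model M = parse_model(model);
  double qdd[NMAX];
  if (!qdd_eval(M, REAL(q), REAL(qd), REAL(tau), force, qdd))
    stop("singular mass matrix");
  return NumericVector(qdd, qdd + M.n);
}

// [[Rcpp::export]]
NumericVector cpp_energies(List model, NumericVector q, NumericVector qd) {
  Model M = parse_model(model);
  double Mq[NMAX][NMAX];
  mass_matrix(M, REAL(q), Mq);
  double T = 0.0;
  for (int r = 0; r < M.n; ++r)
    for (int c = 0; c < M.n; ++c) T += 0.5 * qd[r] * Mq[r][c] * qd[c];
  double phi[NB], sp[NB], cp[NB];
  angles(M, REAL(q), phi, sp, cp);
  double V = M.m_foot * M.g * M.foot_cz;
  for (int i = 0; i < NB; ++i) {
    double z = M.h0;
    for (int j = 0; j < NB; ++j) z += M.a[i][j] * cp[j];
    V += M.mb[i] * M.g * z;
  }
  return NumericVector::create(_["T"] = T, _["V"] = V);
}

// [[Rcpp::export]]
NumericVector cpp_com(List model, NumericVector q, NumericVector qd) {
  Model M = parse_model(model);
  double phi[NB], sp[NB], cp[NB], Jx[NMAX], Jz[NMAX];
  angles(M, REAL(q), phi, sp, cp);
  double sx = M.m_foot * M.foot_cx, sz = M.m_foot * M.foot_cz, svx = 0.0;
  for (int i = 0; i < NB; ++i) {
    double x = 0.0, z = M.h0;
    for (int j = 0; j < NB; ++j) {
      x += M.a[i][j] * sp[j];
      z += M.a[i][j] * cp[j];
    }
    sx += M.mb[i] * x;
    sz += M.mb[i] * z;
    body_jac(M, i, sp, cp, Jx, Jz);
    double vx = 0.0;
    for (int k = 0; k < M.n; ++k) vx += Jx[k] * qd[k];
    svx += M.mb[i] * vx;
  }
  return NumericVector::create(_["x"] = sx / M.m_tot - M.com_x_off,
                               _["z"] = sz / M.m_tot,
                               _["vx"] = svx / M.m_tot);
}

// [[Rcpp::export]]
NumericVector cpp_rk4_step(List model, NumericVector x, NumericVector tau,
                           double force, double dt) {
  Model M = parse_model(model);
  double xs[NSMAX];
  std::memcpy(xs, REAL(x), 2 * M.n * sizeof(double));
  if (!rk4_step(M, xs, REAL(tau), force, dt)) stop("singular mass matrix");
  return NumericVector(xs, xs + 2 * M.n);
}

// [[Rcpp::export]]
NumericMatrix cpp_rollout(List model, NumericVector x0, NumericMatrix tau,
                          NumericVector push, double dt) {
  Model M = parse_model(model);
  int Nt = tau.ncol(), n2 = 2 * M.n;
  if (tau.nrow() != M.nu) stop("torque sequence has wrong row count");
  if (push.size() != Nt) stop("push preview length mismatch");
  NumericMatrix X(n2, Nt + 1);
  double xs[NSMAX];
  std::memcpy(xs, REAL(x0), n2 * sizeof(double));
  for (int i = 0; i < n2; ++i) X(i, 0) = xs[i];
  double u[NMAX];
  for (int k = 0; k < Nt; ++k) {
    for (int i = 0; i < M.nu; ++i) u[i] = tau(i, k);
    if (!rk4_step(M, xs, u, push[k], dt)) stop("singular mass matrix");
    for (int i = 0; i < n2; ++i) X(i, k + 1) = xs[i];
  }
  return X;
}
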