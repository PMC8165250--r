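// Finite-horizon constrained optimal control solver: iterated LQR with a
// box-constrained feedforward QP at every backward step (torque limits)
// and an augmented Lagrangian over the state boxes (joint angle limits).
//
// The transcription is single shooting with time-varying state feedback:
// every forward pass rolls the RK4 dynamics out under
// u = U + alpha*du + K dx, which keeps the unstable pendulum family
// tractable.  Regularisation follows the classic scheme: on backward-pass
// failure (non-PD control Hessian) or forward-pass failure the
// regulariser grows; it decays after accepted steps.

#include "model.h"
#include <vector>
#include <limits>

using namespace Rcpp;
using namespace armbalance;

namespace {

constexpr double BIG = 1e100;

struct Work {
  Model M;
  int Nt, ns, nu;
  double dt, fd_h;
  std::vector<double> push;      // Nt
  std::vector<double> qw, qfw;   // ns
  std::vector<double> rw;        // nu
  std::vector<double> tlo, thi;  // nu
  std::vector<double> xlo, xhi;  // ns
  std::vector<double> lamlo, lamhi;  // ns x Nt (samples 1..Nt)
  double mu;
};

// Augmented-Lagrangian penalty for inequality g <= 0.
inline double al_val(double lam, double mu, double g) {
  double t = lam + mu * g;
  return t > 0.0 ? (t * t - lam * lam) / (2.0 * mu)
                 : -lam * lam / (2.0 * mu);
}
inline double al_grad(double lam, double mu, double g) {
  double t = lam + mu * g;
  return t > 0.0 ? t : 0.0;
}

// state-sample cost (k = 1..Nt): quadratic + AL box terms
double state_cost(const Work& W, const double* x, int k, bool terminal) {
  double J = 0.0;
  const std::vector<double>& wq = terminal ? W.qfw : W.qw;
  for (int i = 0; i < W.ns; ++i) J += 0.5 * wq[i] * x[i] * x[i];
  const double* llo = &W.lamlo[(std::size_t)(k - 1) * W.ns];
  const double* lhi = &W.lamhi[(std::size_t)(k - 1) * W.ns];
  for (int i = 0; i < W.ns; ++i) {
    if (std::isfinite(W.xhi[i])) J += al_val(lhi[i], W.mu, x[i] - W.xhi[i]);
    if (std::isfinite(W.xlo[i])) J += al_val(llo[i], W.mu, W.xlo[i] - x[i]);
  }
  return J;
}

void state_cost_derivs(const Work& W, const double* x, int k, bool terminal,
                       double* lx, double* lxx_diag) {
  const std::vector<double>& wq = terminal ? W.qfw : W.qw;
  const double* llo = &W.lamlo[(std::size_t)(k - 1) * W.ns];
  const double* lhi = &W.lamhi[(std::size_t)(k - 1) * W.ns];
  for (int i = 0; i < W.ns; ++i) {
    lx[i] = wq[i] * x[i];
    lxx_diag[i] = wq[i];
    if (std::isfinite(W.xhi[i])) {
      double t = al_grad(lhi[i], W.mu, x[i] - W.xhi[i]);
      lx[i] += t;
      if (t > 0.0) lxx_diag[i] += W.mu;
    }
    if (std::isfinite(W.xlo[i])) {
      double t = al_grad(llo[i], W.mu, W.xlo[i] - x[i]);
      lx[i] -= t;
      if (t > 0.0) lxx_diag[i] += W.mu;
    }
  }
}

// total cost of a trajectory (stage k=0 uses the fixed x0)
double traj_cost(const Work& W, const double* X, const double* U) {
  double J = 0.0;
  for (int k = 0; k < W.Nt; ++k) {
    const double* x = X + (std::size_t)k * W.ns;
    const double* u = U + (std::size_t)k * W.nu;
    if (k == 0) {
      for (int i = 0; i < W.ns; ++i) J += 0.5 * W.qw[i] * x[i] * x[i];
    } else {
      J += state_cost(W, x, k, false);
    }
    for (int i = 0; i < W.nu; ++i) J += 0.5 * W.rw[i] * u[i] * u[i];
  }
  J += state_cost(W, X + (std::size_t)W.Nt * W.ns, W.Nt, true);
  return J;
}

// open- or closed-loop rollout; returns false on divergence
bool rollout(const Work& W, const double* x0, const double* Uref,
             const double* Xref, const double* DU, const double* K,
             double alpha, double* X, double* U) {
  int ns = W.ns, nu = W.nu;
  std::memcpy(X, x0, ns * sizeof(double));
  for (int k = 0; k < W.Nt; ++k) {
    const double* xk = X + (std::size_t)k * ns;
    double* uk = U + (std::size_t)k * nu;
    const double* ur = Uref + (std::size_t)k * nu;
    for (int i = 0; i < nu; ++i) {
      double v = ur[i];
      if (DU) v += alpha * DU[(std::size_t)k * nu + i];
      if (K && Xref) {
        const double* Kk = K + (std::size_t)k * nu * ns;
        const double* xr = Xref + (std::size_t)k * ns;
        for (int j = 0; j < ns; ++j) v += Kk[i * ns + j] * (xk[j] - xr[j]);
      }
      if (v < W.tlo[i]) v = W.tlo[i];
      if (v > W.thi[i]) v = W.thi[i];
      uk[i] = v;
    }
    double* xn = X + (std::size_t)(k + 1) * ns;
    std::memcpy(xn, xk, ns * sizeof(double));
    if (!rk4_step(W.M, xn, uk, W.push[k], W.dt)) return false;
    for (int i = 0; i < ns; ++i)
      if (!std::isfinite(xn[i]) || std::fabs(xn[i]) > 1e4) return false;
  }
  return true;
}

// central-difference Jacobians of the one-step map
void step_jacobians(const Work& W, const double* x, const double* u, int k,
                    double* A, double* B) {
  int ns = W.ns, nu = W.nu;
  double xp[NSMAX], xm[NSMAX], pert[NSMAX], up[NMAX];
  double h = W.fd_h;
  for (int j = 0; j < ns; ++j) {
    std::memcpy(pert, x, ns * sizeof(double));
    pert[j] = x[j] + h;
    std::memcpy(xp, pert, ns * sizeof(double));
    rk4_step(W.M, xp, u, W.push[k], W.dt);
    pert[j] = x[j] - h;
    std::memcpy(xm, pert, ns * sizeof(double));
    rk4_step(W.M, xm, u, W.push[k], W.dt);
    for (int i = 0; i < ns; ++i)
      A[i * ns + j] = (xp[i] - xm[i]) / (2.0 * h);
  }
  for (int j = 0; j < nu; ++j) {
    std::memcpy(up, u, nu * sizeof(double));
    up[j] = u[j] + h;
    std::memcpy(xp, x, ns * sizeof(double));
    rk4_step(W.M, xp, up, W.push[k], W.dt);
    up[j] = u[j] - h;
    std::memcpy(xm, x, ns * sizeof(double));
    rk4_step(W.M, xm, up, W.push[k], W.dt);
    for (int i = 0; i < ns; ++i)
      B[i * nu + j] = (xp[i] - xm[i]) / (2.0 * h);
  }
}

// Cholesky of an m x m matrix (m <= 3); returns false if not PD.
bool chol3(int m, const double* H, double* L) {
  for (int i = 0; i < m * m; ++i) L[i] = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = H[i * m + j];
      for (int t = 0; t < j; ++t) s -= L[i * m + t] * L[j * m + t];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * m + i] = std::sqrt(s);
      } else {
        L[i * m + j] = s / L[j * m + j];
      }
    }
  }
  return true;
}

void chol_solve(int m, const double* L, const double* b, double* x) {
  double y[NMAX];
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int t = 0; t < i; ++t) s -= L[i * m + t] * y[t];
    y[i] = s / L[i * m + i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = y[i];
    for (int t = i + 1; t < m; ++t) s -= L[t * m + i] * x[t];
    x[i] = s / L[i * m + i];
  }
}

// Projected-Newton box QP: min 0.5 du'H du + q'du, bl <= du <= bu.
// Returns false if a free-set Hessian block is not PD.
bool box_qp(int nu, const double* H, const double* q, const double* bl,
            const double* bu, double* du, bool* freeset) {
  const double eps = 1e-10;
  for (int i = 0; i < nu; ++i) {
    if (du[i] < bl[i]) du[i] = bl[i];
    if (du[i] > bu[i]) du[i] = bu[i];
  }
  auto qobj = [&](const double* v) {
    double s = 0.0;
    for (int i = 0; i < nu; ++i) {
      s += q[i] * v[i];
      for (int j = 0; j < nu; ++j) s += 0.5 * v[i] * H[i * nu + j] * v[j];
    }
    return s;
  };
  for (int it = 0; it < 60; ++it) {
    double g[NMAX];
    for (int i = 0; i < nu; ++i) {
      g[i] = q[i];
      for (int j = 0; j < nu; ++j) g[i] += H[i * nu + j] * du[j];
    }
    int nf = 0, idx[NMAX];
    for (int i = 0; i < nu; ++i) {
      bool cl = (du[i] <= bl[i] + eps && g[i] > 0.0) ||
                (du[i] >= bu[i] - eps && g[i] < 0.0);
      freeset[i] = !cl;
      if (!cl) idx[nf++] = i;
    }
    if (nf == 0) return true;
    double Hf[NMAX * NMAX], gf[NMAX], Lf[NMAX * NMAX], d[NMAX];
    for (int a = 0; a < nf; ++a) {
      gf[a] = g[idx[a]];
      for (int b = 0; b < nf; ++b) Hf[a * nf + b] = H[idx[a] * nu + idx[b]];
    }
    if (!chol3(nf, Hf, Lf)) return false;
    chol_solve(nf, Lf, gf, d);
    double dn = 0.0;
    for (int a = 0; a < nf; ++a) dn = std::max(dn, std::fabs(d[a]));
    if (dn < 1e-12) return true;
    double f0 = qobj(du), t = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 20; ++ls) {
      double cand[NMAX];
      std::memcpy(cand, du, nu * sizeof(double));
      for (int a = 0; a < nf; ++a) {
        int i = idx[a];
        cand[i] = du[i] - t * d[a];
        if (cand[i] < bl[i]) cand[i] = bl[i];
        if (cand[i] > bu[i]) cand[i] = bu[i];
      }
      if (qobj(cand) < f0 - 1e-14) {
        std::memcpy(du, cand, nu * sizeof(double));
        moved = true;
        break;
      }
      t *= 0.5;
    }
    if (!moved) return true;
  }
  return true;
}

struct SolveResult {
  std::vector<double> X, U;
  double cost_al, viol;
  int iters;
  bool stalled;
};

// iLQR on the AL-augmented objective for fixed multipliers/penalty.
SolveResult ilqr(const Work& W, const double* x0, std::vector<double> U,
                 int max_iter, double tol) {
  int ns = W.ns, nu = W.nu, Nt = W.Nt;
  std::vector<double> X((std::size_t)(Nt + 1) * ns);
  std::vector<double> Xn(X.size()), Un(U.size());
  std::vector<double> A((std::size_t)Nt * ns * ns),
      B((std::size_t)Nt * ns * nu), K((std::size_t)Nt * nu * ns),
      DU((std::size_t)Nt * nu);
  SolveResult R;
  R.stalled = false;

  if (!rollout(W, x0, U.data(), nullptr, nullptr, nullptr, 0.0, X.data(),
               U.data())) {
    // clamped-torque open-loop rollout diverged: fall back to zero torques
    std::fill(U.begin(), U.end(), 0.0);
    for (int i = 0; i < nu; ++i) {
      double z = std::min(std::max(0.0, W.tlo[i]), W.thi[i]);
      for (int k = 0; k < Nt; ++k) U[(std::size_t)k * nu + i] = z;
    }
    rollout(W, x0, U.data(), nullptr, nullptr, nullptr, 0.0, X.data(),
            U.data());
  }
  double J = traj_cost(W, X.data(), U.data());
  double reg = 0.0;
  const double reg_min = 1e-8, reg_max = 1e10;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    for (int k = 0; k < Nt; ++k)
      step_jacobians(W, &X[(std::size_t)k * ns], &U[(std::size_t)k * nu],
                     k, &A[(std::size_t)k * ns * ns],
                     &B[(std::size_t)k * ns * nu]);

    bool bp_ok = false;
    double d1 = 0.0, d2 = 0.0;
    while (!bp_ok) {
      bp_ok = true;
      d1 = d2 = 0.0;
      double Vx[NSMAX], Vxx[NSMAX * NSMAX], lx[NSMAX], lxxd[NSMAX];
      state_cost_derivs(W, &X[(std::size_t)Nt * ns], Nt, true, Vx, lxxd);
      for (int i = 0; i < ns * ns; ++i) Vxx[i] = 0.0;
      for (int i = 0; i < ns; ++i) Vxx[i * ns + i] = lxxd[i];
      for (int k = Nt - 1; k >= 0; --k) {
        const double* Ak = &A[(std::size_t)k * ns * ns];
        const double* Bk = &B[(std::size_t)k * ns * nu];
        const double* xk = &X[(std::size_t)k * ns];
        const double* uk = &U[(std::size_t)k * nu];
        // Qx = lx + A'Vx ; Qu = lu + B'Vx
        double Qx[NSMAX], Qu[NMAX];
        if (k == 0) {
          for (int i = 0; i < ns; ++i) {
            lx[i] = W.qw[i] * xk[i];
            lxxd[i] = W.qw[i];
          }
        } else {
          state_cost_derivs(W, xk, k, false, lx, lxxd);
        }
        for (int i = 0; i < ns; ++i) {
          double s = lx[i];
          for (int j = 0; j < ns; ++j) s += Ak[j * ns + i] * Vx[j];
          Qx[i] = s;
        }
        for (int i = 0; i < nu; ++i) {
          double s = W.rw[i] * uk[i];
          for (int j = 0; j < ns; ++j) s += Bk[j * nu + i] * Vx[j];
          Qu[i] = s;
        }
        // M1 = Vxx*A (ns x ns), M2 = Vxx*B (ns x nu); the regularised
        // variants add reg * A / reg * B inside the products
        double Qxx[NSMAX * NSMAX], Qux[NMAX * NSMAX], Quu[NMAX * NMAX];
        double Qux_r[NMAX * NSMAX], Quu_r[NMAX * NMAX];
        double M1[NSMAX * NSMAX], M2[NSMAX * NMAX];
        for (int i = 0; i < ns; ++i)
          for (int j = 0; j < ns; ++j) {
            double s = 0.0;
            for (int a = 0; a < ns; ++a) s += Vxx[i * ns + a] * Ak[a * ns + j];
            M1[i * ns + j] = s;
          }
        for (int i = 0; i < ns; ++i)
          for (int j = 0; j < nu; ++j) {
            double s = 0.0;
            for (int a = 0; a < ns; ++a) s += Vxx[i * ns + a] * Bk[a * nu + j];
            M2[i * nu + j] = s;
          }
        for (int i = 0; i < ns; ++i)
          for (int j = 0; j < ns; ++j) {
            double s = (i == j) ? lxxd[i] : 0.0;
            for (int a = 0; a < ns; ++a) s += Ak[a * ns + i] * M1[a * ns + j];
            Qxx[i * ns + j] = s;
          }
        for (int i = 0; i < nu; ++i)
          for (int j = 0; j < ns; ++j) {
            double s = 0.0, sr = 0.0;
            for (int a = 0; a < ns; ++a) {
              s += Bk[a * nu + i] * M1[a * ns + j];
              sr += Bk[a * nu + i] *
                    (M1[a * ns + j] + reg * Ak[a * ns + j]);
            }
            Qux[i * ns + j] = s;
            Qux_r[i * ns + j] = sr;
          }
        for (int i = 0; i < nu; ++i)
          for (int j = 0; j < nu; ++j) {
            double s = (i == j) ? W.rw[i] : 0.0, sr = s;
            for (int a = 0; a < ns; ++a) {
              s += Bk[a * nu + i] * M2[a * nu + j];
              sr += Bk[a * nu + i] * (M2[a * nu + j] + reg * Bk[a * nu + j]);
            }
            Quu[i * nu + j] = s;
            Quu_r[i * nu + j] = sr;
          }
        // box QP for the feedforward step
        double bl[NMAX], bu[NMAX], du[NMAX];
        bool freeset[NMAX];
        for (int i = 0; i < nu; ++i) {
          bl[i] = W.tlo[i] - uk[i];
          bu[i] = W.thi[i] - uk[i];
          du[i] = DU[(std::size_t)k * nu + i];
        }
        if (!box_qp(nu, Quu_r, Qu, bl, bu, du, freeset)) {
          bp_ok = false;
          break;
        }
        // gains on the free subspace
        double* Kk = &K[(std::size_t)k * nu * ns];
        for (int i = 0; i < nu * ns; ++i) Kk[i] = 0.0;
        int nf = 0, idx[NMAX];
        for (int i = 0; i < nu; ++i)
          if (freeset[i]) idx[nf++] = i;
        if (nf > 0) {
          double Hf[NMAX * NMAX], Lf[NMAX * NMAX];
          for (int a = 0; a < nf; ++a)
            for (int b = 0; b < nf; ++b)
              Hf[a * nf + b] = Quu_r[idx[a] * nu + idx[b]];
          if (!chol3(nf, Hf, Lf)) {
            bp_ok = false;
            break;
          }
          for (int j = 0; j < ns; ++j) {
            double rhs[NMAX], sol[NMAX];
            for (int a = 0; a < nf; ++a) rhs[a] = Qux_r[idx[a] * ns + j];
            chol_solve(nf, Lf, rhs, sol);
            for (int a = 0; a < nf; ++a) Kk[idx[a] * ns + j] = -sol[a];
          }
        }
        for (int i = 0; i < nu; ++i) DU[(std::size_t)k * nu + i] = du[i];
        // expected-improvement bookkeeping
        for (int i = 0; i < nu; ++i) {
          d1 += du[i] * Qu[i];
          for (int j = 0; j < nu; ++j)
            d2 += du[i] * Quu[i * nu + j] * du[j];
        }
        // value update (Tassa-style, with du and K)
        double Qu_Kdu[NSMAX];  // K'(Quu du + Qu) + Qux' du
        double tmpu[NMAX];
        for (int i = 0; i < nu; ++i) {
          double s = Qu[i];
          for (int j = 0; j < nu; ++j) s += Quu[i * nu + j] * du[j];
          tmpu[i] = s;
        }
        for (int j = 0; j < ns; ++j) {
          double s = 0.0;
          for (int i = 0; i < nu; ++i) {
            s += Kk[i * ns + j] * tmpu[i] + Qux[i * ns + j] * du[i];
          }
          Qu_Kdu[j] = s;
        }
        double Vx_new[NSMAX], Vxx_new[NSMAX * NSMAX];
        for (int j = 0; j < ns; ++j) Vx_new[j] = Qx[j] + Qu_Kdu[j];
        // Vxx = Qxx + K'Quu K + K'Qux + Qux'K, with T1 = Quu*K
        double T1[NMAX * NSMAX];
        for (int a = 0; a < nu; ++a)
          for (int j = 0; j < ns; ++j) {
            double s = 0.0;
            for (int b = 0; b < nu; ++b)
              s += Quu[a * nu + b] * Kk[b * ns + j];
            T1[a * ns + j] = s;
          }
        for (int i = 0; i < ns; ++i)
          for (int j = 0; j < ns; ++j) {
            double s = Qxx[i * ns + j];
            for (int a = 0; a < nu; ++a) {
              s += Kk[a * ns + i] * T1[a * ns + j];
              s += Kk[a * ns + i] * Qux[a * ns + j];
              s += Qux[a * ns + i] * Kk[a * ns + j];
            }
            Vxx_new[i * ns + j] = s;
          }
        std::memcpy(Vx, Vx_new, ns * sizeof(double));
        for (int i = 0; i < ns; ++i)
          for (int j = 0; j < ns; ++j)
            Vxx[i * ns + j] =
                0.5 * (Vxx_new[i * ns + j] + Vxx_new[j * ns + i]);
      }
      if (!bp_ok) {
        reg = std::max(reg * 10.0, reg_min);
        if (reg > reg_max) {
          R.stalled = true;
          break;
        }
      }
    }
    if (R.stalled) break;

    // forward pass with backtracking line search
    double alpha = 1.0;
    bool accepted = false;
    for (int ls = 0; ls < 12; ++ls) {
      if (rollout(W, x0, U.data(), X.data(), DU.data(), K.data(), alpha,
                  Xn.data(), Un.data())) {
        double Jn = traj_cost(W, Xn.data(), Un.data());
        double expect = -(alpha * d1 + 0.5 * alpha * alpha * d2);
        if (Jn <= J - 1e-4 * std::max(expect, 0.0) &&
            Jn < J + 1e-12 * std::fabs(J) + 1e-12) {
          double dJ = J - Jn;
          X.swap(Xn);
          U.swap(Un);
          J = Jn;
          accepted = true;
          reg = (reg > reg_min) ? reg * 0.3 : 0.0;
          if (dJ < tol * std::max(1.0, std::fabs(J))) {
            iter = iter + 1;
            goto done;
          }
          break;
        }
      }
      alpha *= 0.5;
    }
    if (!accepted) {
      reg = std::max(reg * 10.0, reg_min);
      if (reg > reg_max) {
        R.stalled = true;
        break;
      }
    }
    std::fill(DU.begin(), DU.end(), 0.0);
  }
done:
  R.X = std::move(X);
  R.U = std::move(U);
  R.cost_al = J;
  R.iters = iter;
  // worst state-box violation over samples 1..Nt
  double v = 0.0;
  for (int k = 1; k <= Nt; ++k) {
    const double* x = &R.X[(std::size_t)k * ns];
    for (int i = 0; i < ns; ++i) {
      if (std::isfinite(W.xhi[i])) v = std::max(v, x[i] - W.xhi[i]);
      if (std::isfinite(W.xlo[i])) v = std::max(v, W.xlo[i] - x[i]);
    }
  }
  R.viol = v;
  return R;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ocp_solve(List model, NumericVector x0, NumericVector push,
                   double dt, NumericVector qw, NumericVector rw,
                   NumericVector qfw, NumericVector tau_lo,
                   NumericVector tau_hi, NumericVector x_lo,
                   NumericVector x_hi, NumericMatrix U0,
                   NumericMatrix lamlo0, NumericMatrix lamhi0, double mu0,
                   double mu_growth, int outer_max, double feas_tol,
                   double infeas_tol, int max_iter, double tol,
                   double fd_h) {
  Work W;
  W.M = parse_model(model);
  W.Nt = push.size();
  W.ns = 2 * W.M.n;
  W.nu = W.M.nu;
  W.dt = dt;
  W.fd_h = fd_h;
  W.push.assign(push.begin(), push.end());
  W.qw.assign(qw.begin(), qw.end());
  W.qfw.assign(qfw.begin(), qfw.end());
  W.rw.assign(rw.begin(), rw.end());
  W.tlo.assign(tau_lo.begin(), tau_lo.end());
  W.thi.assign(tau_hi.begin(), tau_hi.end());
  W.xlo.assign(x_lo.begin(), x_lo.end());
  W.xhi.assign(x_hi.begin(), x_hi.end());
  int ns = W.ns, nu = W.nu, Nt = W.Nt;
  W.lamlo.assign((std::size_t)Nt * ns, 0.0);
  W.lamhi.assign((std::size_t)Nt * ns, 0.0);
  for (int k = 0; k < Nt; ++k)
    for (int i = 0; i < ns; ++i) {
      W.lamlo[(std::size_t)k * ns + i] = lamlo0(i, k);
      W.lamhi[(std::size_t)k * ns + i] = lamhi0(i, k);
    }
  W.mu = mu0;

  std::vector<double> U((std::size_t)Nt * nu);
  for (int k = 0; k < Nt; ++k)
    for (int i = 0; i < nu; ++i) {
      double v = U0(i, k);
      if (v < W.tlo[i]) v = W.tlo[i];
      if (v > W.thi[i]) v = W.thi[i];
      U[(std::size_t)k * nu + i] = v;
    }

  SolveResult R;
  double viol_prev = std::numeric_limits<double>::infinity();
  int outer = 0, total_iters = 0;
  bool any_finite_box = false;
  for (int i = 0; i < ns; ++i)
    if (std::isfinite(W.xlo[i]) || std::isfinite(W.xhi[i]))
      any_finite_box = true;
  for (outer = 1; outer <= outer_max; ++outer) {
    R = ilqr(W, REAL(x0), U, max_iter, tol);
    U = R.U;
    total_iters += R.iters;
    if (!any_finite_box || R.viol <= feas_tol) break;
    if (outer == outer_max) break;
    // multiplier update
    for (int k = 1; k <= Nt; ++k) {
      const double* x = &R.X[(std::size_t)k * ns];
      for (int i = 0; i < ns; ++i) {
        std::size_t id = (std::size_t)(k - 1) * ns + i;
        if (std::isfinite(W.xhi[i]))
          W.lamhi[id] = al_grad(W.lamhi[id], W.mu, x[i] - W.xhi[i]);
        if (std::isfinite(W.xlo[i]))
          W.lamlo[id] = al_grad(W.lamlo[id], W.mu, W.xlo[i] - x[i]);
      }
    }
    if (R.viol > 0.25 * viol_prev && W.mu < 1e11) W.mu *= mu_growth;
    viol_prev = R.viol;
  }

  // pure quadratic cost of the accepted trajectory
  double Jq = 0.0;
  for (int k = 0; k <= Nt; ++k) {
    const double* x = &R.X[(std::size_t)k * ns];
    const std::vector<double>& wq = (k == Nt) ? W.qfw : W.qw;
    for (int i = 0; i < ns; ++i) Jq += 0.5 * wq[i] * x[i] * x[i];
    if (k < Nt) {
      const double* u = &U[(std::size_t)k * nu];
      for (int i = 0; i < nu; ++i) Jq += 0.5 * W.rw[i] * u[i] * u[i];
    }
  }

  std::string status;
  if (R.viol <= feas_tol) status = "optimal";
  else if (R.viol > infeas_tol) status = "infeasible";
  else status = "max_iter";

  NumericMatrix Uo(nu, Nt), Xo(ns, Nt + 1), Llo(ns, Nt), Lhi(ns, Nt);
  for (int k = 0; k < Nt; ++k)
    for (int i = 0; i < nu; ++i) Uo(i, k) = U[(std::size_t)k * nu + i];
  for (int k = 0; k <= Nt; ++k)
    for (int i = 0; i < ns; ++i) Xo(i, k) = R.X[(std::size_t)k * ns + i];
  for (int k = 0; k < Nt; ++k)
    for (int i = 0; i < ns; ++i) {
      Llo(i, k) = W.lamlo[(std::size_t)k * ns + i];
      Lhi(i, k) = W.lamhi[(std::size_t)k * ns + i];
    }
  return List::create(
      _["tau"] = Uo, _["X"] = Xo, _["cost"] = Jq, _["cost_al"] = R.cost_al,
      _["status"] = status, _["violation"] = R.viol,
      _["outer_iterations"] = outer, _["ilqr_iterations"] = total_iters,
      _["lamlo"] = Llo, _["lamhi"] = Lhi, _["mu"] = W.mu,
      _["stalled"] = R.stalled);
}
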