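// Forward model: bilinear neural dynamics + balloon hemodynamics, integrated
// with classical RK4 at microtime resolution. Inputs are piecewise-constant
// per microtime bin and encoded as an index into a small set of distinct
// input combinations, so the effective coupling matrix (A + sum_j u_j B^j)
// and the direct drive C u are precomputed once per combination. The inner
// loop works on flat arrays: this routine is called O(p) times per
// Gauss-Newton iteration to linearize the model by finite differences.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Work {
  int n;
  const double* Aeff;      // n*n per combo, column-major, concatenated
  const double* Cu;        // n per combo, concatenated
  const double* kappa;
  const double* gamma;
  const double* tau;
  const double* inv_alpha;
  const double* log1mrho;
  const double* rho;
  const double* epsilon;
};

// State layout: z[0..n), s[n..2n), f[2n..3n), v[3n..4n), q[4n..5n).
inline void deriv(const Work& w, int combo, const double* x, double* dx) {
  const int n = w.n;
  const double* A = w.Aeff + static_cast<size_t>(combo) * n * n;
  const double* d = w.Cu + static_cast<size_t>(combo) * n;
  const double* z = x;
  const double* s = x + n;
  const double* f = x + 2 * n;
  const double* v = x + 3 * n;
  const double* q = x + 4 * n;
  for (int i = 0; i < n; ++i) {
    double acc = d[i];
    for (int j = 0; j < n; ++j) acc += A[i + j * n] * z[j];
    dx[i] = acc;
  }
  for (int i = 0; i < n; ++i) {
    const double fi = f[i], vi = v[i];
    const double fv = std::exp(std::log(vi) * w.inv_alpha[i]);  // v^(1/alpha)
    const double E = 1.0 - std::exp(w.log1mrho[i] / fi);        // O2 extraction
    dx[n + i] = w.epsilon[i] * z[i] - w.kappa[i] * s[i] - w.gamma[i] * (fi - 1.0);
    dx[2 * n + i] = s[i];
    dx[3 * n + i] = (fi - fv) / w.tau[i];
    dx[4 * n + i] = (fi * E / w.rho[i] - fv * q[i] / vi) / w.tau[i];
  }
}

inline bool bad_state(const double* x, int n) {
  for (int i = 0; i < 5 * n; ++i) {
    if (!std::isfinite(x[i])) return true;
  }
  for (int i = 0; i < n; ++i) {
    if (std::fabs(x[i]) > 1e6) return true;                  // neural blow-up
    if (x[2 * n + i] <= 0 || x[3 * n + i] <= 0 || x[4 * n + i] <= 0)
      return true;                                           // f, v, q > 0
  }
  return false;
}

}  // namespace

// Integrate one run of n_vol volumes. Ucombo is (n_combo x m); combo_idx maps
// each of the n_vol*bins_per_tr microtime bins to a row of Ucombo (1-based).
// BOLD is sampled at the end of each volume. Returns list(y, diverged).
// [[Rcpp::export]]
Rcpp::List dcm_integrate_cpp(const arma::mat& A, const arma::cube& B,
                             const arma::mat& C, const arma::mat& Ucombo,
                             const arma::ivec& combo_idx, int bins_per_tr,
                             double dt, int n_vol, const arma::vec& kappa,
                             const arma::vec& gamma, const arma::vec& tau,
                             const arma::vec& alpha, const arma::vec& rho,
                             const arma::vec& V0, const arma::vec& epsilon) {
  const int n = static_cast<int>(A.n_rows);
  const int m = static_cast<int>(C.n_cols);
  const int n_combo = static_cast<int>(Ucombo.n_rows);
  const int ns = 5 * n;

  // Precompute effective couplings and drives per input combination.
  std::vector<double> Aeff(static_cast<size_t>(n_combo) * n * n);
  std::vector<double> Cu(static_cast<size_t>(n_combo) * n);
  for (int c = 0; c < n_combo; ++c) {
    arma::mat M = A;
    for (int j = 0; j < m; ++j) M += Ucombo(c, j) * B.slice(j);
    std::copy(M.begin(), M.end(), Aeff.begin() + static_cast<size_t>(c) * n * n);
    arma::vec d = C * Ucombo.row(c).t();
    std::copy(d.begin(), d.end(), Cu.begin() + static_cast<size_t>(c) * n);
  }

  std::vector<double> inv_alpha(n), log1mrho(n);
  for (int i = 0; i < n; ++i) {
    inv_alpha[i] = 1.0 / alpha[i];
    log1mrho[i] = std::log(1.0 - rho[i]);
  }

  Work w{n, Aeff.data(), Cu.data(), kappa.memptr(), gamma.memptr(),
         tau.memptr(), inv_alpha.data(), log1mrho.data(), rho.memptr(),
         epsilon.memptr()};

  std::vector<double> x(ns, 0.0), xt(ns), k1(ns), k2(ns), k3(ns), k4(ns);
  for (int i = 2 * n; i < ns; ++i) x[i] = 1.0;  // f = v = q = 1 at rest

  arma::mat y(n_vol, n, arma::fill::zeros);
  bool diverged = false;
  const double h2 = 0.5 * dt, h6 = dt / 6.0;
  size_t bin = 0;
  for (int vol = 0; vol < n_vol && !diverged; ++vol) {
    for (int b = 0; b < bins_per_tr; ++b, ++bin) {
      const int c = combo_idx[bin] - 1;
      deriv(w, c, x.data(), k1.data());
      for (int i = 0; i < ns; ++i) xt[i] = x[i] + h2 * k1[i];
      deriv(w, c, xt.data(), k2.data());
      for (int i = 0; i < ns; ++i) xt[i] = x[i] + h2 * k2[i];
      deriv(w, c, xt.data(), k3.data());
      for (int i = 0; i < ns; ++i) xt[i] = x[i] + dt * k3[i];
      deriv(w, c, xt.data(), k4.data());
      for (int i = 0; i < ns; ++i) {
        x[i] += h6 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
      }
      if (bad_state(x.data(), n)) { diverged = true; break; }
    }
    if (!diverged) {
      for (int i = 0; i < n; ++i) {
        const double vi = x[3 * n + i], qi = x[4 * n + i];
        const double k1c = 7.0 * rho[i], k2c = 2.0, k3c = 2.0 * rho[i] - 0.2;
        y(vol, i) = V0[i] * (k1c * (1.0 - qi) + k2c * (1.0 - qi / vi) +
                             k3c * (1.0 - vi));
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("diverged") = diverged);
}

// ---------------------------------------------------------------------------
// Forward sensitivities: integrates the augmented system (states + dstate/
// dtheta) with the same RK4 scheme, yielding the exact Jacobian of the
// sampled BOLD with respect to the free coupling (and optional transit-time)
// parameters in a single pass. Parameter spec per column k:
//   kind[k]: 0 = A entry, 1 = B entry, 2 = C entry, 3 = log-tau scale
//   row[k]:  target region (1-based)
//   col[k]:  source region for A/B, input index for C, unused for tau
//   slice[k]: input index for B (1-based), unused otherwise
// Returns list(y [n_vol x n], J [n_vol*n x p], diverged).
// [[Rcpp::export]]
Rcpp::List dcm_sensitivities_cpp(const arma::mat& A, const arma::cube& B,
                                 const arma::mat& C, const arma::mat& Ucombo,
                                 const arma::ivec& combo_idx, int bins_per_tr,
                                 double dt, int n_vol,
                                 const arma::ivec& kind,
                                 const arma::ivec& row, const arma::ivec& col,
                                 const arma::ivec& slice,
                                 const arma::vec& kappa,
                                 const arma::vec& gamma, const arma::vec& tau,
                                 const arma::vec& alpha, const arma::vec& rho,
                                 const arma::vec& V0,
                                 const arma::vec& epsilon) {
  const int n = static_cast<int>(A.n_rows);
  const int m = static_cast<int>(C.n_cols);
  const int n_combo = static_cast<int>(Ucombo.n_rows);
  const int ns = 5 * n;
  const int p = static_cast<int>(kind.n_elem);

  std::vector<double> Aeff(static_cast<size_t>(n_combo) * n * n);
  std::vector<double> Cu(static_cast<size_t>(n_combo) * n);
  for (int c = 0; c < n_combo; ++c) {
    arma::mat M = A;
    for (int j = 0; j < m; ++j) M += Ucombo(c, j) * B.slice(j);
    std::copy(M.begin(), M.end(), Aeff.begin() + static_cast<size_t>(c) * n * n);
    arma::vec d = C * Ucombo.row(c).t();
    std::copy(d.begin(), d.end(), Cu.begin() + static_cast<size_t>(c) * n);
  }
  std::vector<double> inv_alpha(n), log1mrho(n);
  for (int i = 0; i < n; ++i) {
    inv_alpha[i] = 1.0 / alpha[i];
    log1mrho[i] = std::log(1.0 - rho[i]);
  }

  // Scratch for the per-stage local linearization of the hemodynamics.
  std::vector<double> dq_df(n), dq_dv(n), dq_dq(n), dv_df(n), dv_dv(n);
  std::vector<double> Fv(n), Fq(n);  // current v,q derivatives (for tau sens)

  // Base-state derivative that also fills the linearization scratch.
  auto deriv_lin = [&](int c, const double* x, double* dx) {
    const double* Ae = Aeff.data() + static_cast<size_t>(c) * n * n;
    const double* d = Cu.data() + static_cast<size_t>(c) * n;
    const double* z = x;
    const double* s = x + n;
    const double* f = x + 2 * n;
    const double* v = x + 3 * n;
    const double* q = x + 4 * n;
    for (int i = 0; i < n; ++i) {
      double acc = d[i];
      for (int j = 0; j < n; ++j) acc += Ae[i + j * n] * z[j];
      dx[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      const double fi = f[i], vi = v[i], qi = q[i];
      const double ia = inv_alpha[i], ti = tau[i];
      const double fv = std::exp(std::log(vi) * ia);       // v^(1/alpha)
      const double ex = std::exp(log1mrho[i] / fi);        // (1-rho)^(1/f)
      const double E = 1.0 - ex;
      dx[n + i] = epsilon[i] * z[i] - kappa[i] * s[i] - gamma[i] * (fi - 1.0);
      dx[2 * n + i] = s[i];
      Fv[i] = (fi - fv) / ti;
      Fq[i] = (fi * E / rho[i] - fv * qi / vi) / ti;
      dx[3 * n + i] = Fv[i];
      dx[4 * n + i] = Fq[i];
      // partials reused by every sensitivity column
      const double dE_df = ex * log1mrho[i] / (fi * fi);
      dv_df[i] = 1.0 / ti;
      dv_dv[i] = -ia * (fv / vi) / ti;
      dq_df[i] = (E + fi * dE_df) / rho[i] / ti;
      dq_dv[i] = -qi * (ia - 1.0) * (fv / (vi * vi)) / ti;
      dq_dq[i] = -(fv / vi) / ti;
    }
  };

  // Sensitivity derivative for all p columns given the linearization at the
  // current stage state. S and dS are ns x p, column-major.
  auto sens_deriv = [&](int c, const double* x, const double* S, double* dS) {
    const double* Ae = Aeff.data() + static_cast<size_t>(c) * n * n;
    const double* z = x;
    for (int k = 0; k < p; ++k) {
      const double* Sk = S + static_cast<size_t>(k) * ns;
      double* Dk = dS + static_cast<size_t>(k) * ns;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += Ae[i + j * n] * Sk[j];
        Dk[i] = acc;
      }
      for (int i = 0; i < n; ++i) {
        Dk[n + i] = epsilon[i] * Sk[i] - kappa[i] * Sk[n + i] -
                    gamma[i] * Sk[2 * n + i];
        Dk[2 * n + i] = Sk[n + i];
        Dk[3 * n + i] = dv_df[i] * Sk[2 * n + i] + dv_dv[i] * Sk[3 * n + i];
        Dk[4 * n + i] = dq_df[i] * Sk[2 * n + i] + dq_dv[i] * Sk[3 * n + i] +
                        dq_dq[i] * Sk[4 * n + i];
      }
      // explicit dF/dtheta_k term
      const int i = row[k] - 1;
      switch (kind[k]) {
        case 0:  // A[i, col]
          Dk[i] += z[col[k] - 1];
          break;
        case 1:  // B[i, col] for input slice
          Dk[i] += Ucombo(c, slice[k] - 1) * z[col[k] - 1];
          break;
        case 2:  // C[i, input col]
          Dk[i] += Ucombo(c, col[k] - 1);
          break;
        case 3:  // tau_i = tau0_i * exp(theta): dF/dtheta = -F for v,q rows
          Dk[3 * n + i] += -Fv[i];
          Dk[4 * n + i] += -Fq[i];
          break;
      }
    }
  };

  std::vector<double> x(ns, 0.0), xt(ns), k1(ns), k2(ns), k3(ns), k4(ns);
  for (int i = 2 * n; i < ns; ++i) x[i] = 1.0;
  const size_t nsp = static_cast<size_t>(ns) * p;
  std::vector<double> S(nsp, 0.0), St(nsp), S1(nsp), S2(nsp), S3(nsp), S4(nsp);

  arma::mat y(n_vol, n, arma::fill::zeros);
  arma::mat J(static_cast<size_t>(n_vol) * n, p, arma::fill::zeros);
  bool diverged = false;
  const double h2 = 0.5 * dt, h6 = dt / 6.0;
  size_t bin = 0;
  for (int vol = 0; vol < n_vol && !diverged; ++vol) {
    for (int b = 0; b < bins_per_tr; ++b, ++bin) {
      const int c = combo_idx[bin] - 1;
      deriv_lin(c, x.data(), k1.data());
      sens_deriv(c, x.data(), S.data(), S1.data());
      for (int i = 0; i < ns; ++i) xt[i] = x[i] + h2 * k1[i];
      for (size_t i = 0; i < nsp; ++i) St[i] = S[i] + h2 * S1[i];
      deriv_lin(c, xt.data(), k2.data());
      sens_deriv(c, xt.data(), St.data(), S2.data());
      for (int i = 0; i < ns; ++i) xt[i] = x[i] + h2 * k2[i];
      for (size_t i = 0; i < nsp; ++i) St[i] = S[i] + h2 * S2[i];
      deriv_lin(c, xt.data(), k3.data());
      sens_deriv(c, xt.data(), St.data(), S3.data());
      for (int i = 0; i < ns; ++i) xt[i] = x[i] + dt * k3[i];
      for (size_t i = 0; i < nsp; ++i) St[i] = S[i] + dt * S3[i];
      deriv_lin(c, xt.data(), k4.data());
      sens_deriv(c, xt.data(), St.data(), S4.data());
      for (int i = 0; i < ns; ++i) {
        x[i] += h6 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
      }
      for (size_t i = 0; i < nsp; ++i) {
        S[i] += h6 * (S1[i] + 2.0 * (S2[i] + S3[i]) + S4[i]);
      }
      if (bad_state(x.data(), n)) { diverged = true; break; }
    }
    if (!diverged) {
      for (int i = 0; i < n; ++i) {
        const double vi = x[3 * n + i], qi = x[4 * n + i];
        const double k1c = 7.0 * rho[i], k2c = 2.0, k3c = 2.0 * rho[i] - 0.2;
        y(vol, i) = V0[i] * (k1c * (1.0 - qi) + k2c * (1.0 - qi / vi) +
                             k3c * (1.0 - vi));
        const double dy_dv = V0[i] * (k2c * qi / (vi * vi) - k3c);
        const double dy_dq = V0[i] * (-k1c - k2c / vi);
        const size_t r = static_cast<size_t>(vol) + static_cast<size_t>(i) * n_vol;
        for (int k = 0; k < p; ++k) {
          const double* Sk = S.data() + static_cast<size_t>(k) * ns;
          J(r, k) = dy_dv * Sk[3 * n + i] + dy_dq * Sk[4 * n + i];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("J") = J,
                            Rcpp::Named("diverged") = diverged);
}
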