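#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// transfer function with the removable singularity at a*chi == b handled
// by series expansion (matches firing_rate() on the R side)
static inline double rate_fn(double x, double d) {
  if (std::fabs(x) < 1e-9) {
    return 1.0 / d + x / 2.0 + d * x * x / 12.0;
  }
  return x / (1.0 - std::exp(-d * x));
}

// Forward-Euler integration of the coupled reduced Wong-Wang network.
//   dS_i/dt = -S_i/tau_S + (1 - S_i) * gamma_kin * R_i
//   R_i     = rate(a * chi_i - b),  chi_i = w*J_N*S_i + J_N*G*(C S)_i + I_0
// S is clamped to [0,1] after every step. If tol > 0, exits early once
// max_i |dS_i/dt| < tol has held for `hold` consecutive steps.
// [[Rcpp::export]]
List euler_integrate(const arma::mat& C, const arma::vec& S0,
                     double G, double tau_S, double gamma_kin,
                     double a, double b, double d,
                     double w, double J_N, double I_0,
                     double dt, int n_steps,
                     double tol, int hold,
                     bool keep_trajectory, int thin) {
  const arma::uword n = S0.n_elem;
  arma::vec S = S0;
  arma::vec chi(n), dS(n);
  bool converged = false;
  int step = 0, ok_streak = 0;

  arma::mat traj;
  int n_stored = 0;
  if (keep_trajectory) {
    traj.set_size(n_steps / thin + 1, n);
    traj.row(0) = S.t();
    n_stored = 1;
  }

  for (step = 1; step <= n_steps; ++step) {
    chi = w * J_N * S + J_N * G * (C * S) + I_0;
    double m = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double R = rate_fn(a * chi[i] - b, d);
      dS[i] = -S[i] / tau_S + (1.0 - S[i]) * gamma_kin * R;
      double ad = std::fabs(dS[i]);
      if (ad > m) m = ad;
    }
    S += dt * dS;
    S.clamp(0.0, 1.0);
    if (!S.is_finite()) {
      List bad = List::create(_["S"] = S, _["converged"] = false,
                              _["steps"] = step);
      if (keep_trajectory && n_stored > 0) {
        bad["trajectory"] = traj.rows(0, n_stored - 1);
      }
      return bad;
    }
    if (keep_trajectory && step % thin == 0) {
      traj.row(n_stored++) = S.t();
    }
    if (tol > 0) {
      ok_streak = (m < tol) ? ok_streak + 1 : 0;
      if (ok_streak >= hold) { converged = true; break; }
    }
  }
  if (step > n_steps) step = n_steps;

  List out = List::create(_["S"] = S,
                          _["converged"] = converged,
                          _["steps"] = step);
  if (keep_trajectory) out["trajectory"] = traj.rows(0, n_stored - 1);
  return out;
}
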