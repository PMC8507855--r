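// Linear-Gaussian state-space machinery: Kalman filter, RTS smoother, and a
// deterministic simulator. The transition matrix is handled as sparse because
// the daily-seasonal structural model (state dim 49 for 48 slots/day) has a
// shift-register seasonal block that is almost empty.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline bool obs_ok(double y) { return std::isfinite(y); }

// One forward filtering pass. y may contain NA/NaN (treated as missing:
// the update step is skipped and the prediction is carried through).
// a0/P0 are the prior moments of the state at the FIRST time point.
// [[Rcpp::export]]
Rcpp::List cpp_kalman_filter(const arma::mat& Tm, const arma::rowvec& Z,
                             const arma::mat& Rm, const arma::mat& Q,
                             const double H, const arma::vec& a0,
                             const arma::mat& P0, const arma::vec& y,
                             const bool want_cov) {
  const uword k = Tm.n_rows, n = y.n_elem;
  sp_mat Ts(Tm);
  mat RQR = Rm * Q * Rm.t();

  mat a_pred(k, n), a_filt(k, n);
  cube Pp, Pf;
  if (want_cov) { Pp.set_size(k, k, n); Pf.set_size(k, k, n); }
  vec yhat_f(n), yvar_f(n), v_t(n, fill::value(datum::nan)),
      F_t(n, fill::value(datum::nan));

  vec a = a0;
  mat P = P0;
  double ll = 0.0;
  int nobs = 0;
  const double l2pi = std::log(2.0 * datum::pi);

  for (uword t = 0; t < n; ++t) {
    if (t > 0) {                      // predict
      a = Ts * a;
      P = Ts * (Ts * P).t();          // T P T' (P symmetric)
      P = 0.5 * (P + P.t()) + RQR;
    }
    a_pred.col(t) = a;
    if (want_cov) Pp.slice(t) = P;

    rowvec ZP = Z * P;
    double F = dot(ZP, Z) + H;
    yhat_f(t) = dot(Z, a);
    yvar_f(t) = F;

    if (obs_ok(y(t))) {               // update
      double v = y(t) - dot(Z, a);
      if (F <= 0) Rcpp::stop("non-positive innovation variance at t=%d", t + 1);
      vec K = ZP.t() / F;
      a += K * v;
      P -= K * ZP;
      P = 0.5 * (P + P.t());
      ll += -0.5 * (l2pi + std::log(F) + v * v / F);
      v_t(t) = v; F_t(t) = F;
      ++nobs;
    }
    a_filt.col(t) = a;
    if (want_cov) Pf.slice(t) = P;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = ll, Rcpp::Named("n_obs") = nobs,
      Rcpp::Named("a_pred") = a_pred, Rcpp::Named("a_filt") = a_filt,
      Rcpp::Named("yhat_filt") = yhat_f, Rcpp::Named("yvar_filt") = yvar_f,
      Rcpp::Named("innov") = v_t, Rcpp::Named("innov_var") = F_t);
  if (want_cov) { out["P_pred"] = Pp; out["P_filt"] = Pf; }
  return out;
}

// Filter + Rauch-Tung-Striebel backward pass. Returns smoothed state means,
// the smoothed observation estimate Z a_{t|n} and its variance
// Z P_{t|n} Z' + H. Full covariance cubes only on request (small n).
// [[Rcpp::export]]
Rcpp::List cpp_kalman_smooth(const arma::mat& Tm, const arma::rowvec& Z,
                             const arma::mat& Rm, const arma::mat& Q,
                             const double H, const arma::vec& a0,
                             const arma::mat& P0, const arma::vec& y,
                             const bool want_cov) {
  const uword k = Tm.n_rows, n = y.n_elem;
  sp_mat Ts(Tm);
  mat RQR = Rm * Q * Rm.t();

  mat a_pred(k, n), a_filt(k, n);
  cube Pp(k, k, n), Pf(k, k, n);

  vec a = a0;
  mat P = P0;
  double ll = 0.0;
  const double l2pi = std::log(2.0 * datum::pi);

  for (uword t = 0; t < n; ++t) {
    if (t > 0) {
      a = Ts * a;
      P = Ts * (Ts * P).t();
      P = 0.5 * (P + P.t()) + RQR;
    }
    a_pred.col(t) = a;
    Pp.slice(t) = P;
    if (obs_ok(y(t))) {
      rowvec ZP = Z * P;
      double F = dot(ZP, Z) + H;
      if (F <= 0) Rcpp::stop("non-positive innovation variance at t=%d", t + 1);
      double v = y(t) - dot(Z, a);
      vec K = ZP.t() / F;
      a += K * v;
      P -= K * ZP;
      P = 0.5 * (P + P.t());
      ll += -0.5 * (l2pi + std::log(F) + v * v / F);
    }
    a_filt.col(t) = a;
    Pf.slice(t) = P;
  }

  // backward recursion; smoothed moments overwrite the filtered copies
  mat a_sm(k, n);
  cube Ps;
  if (want_cov) Ps.set_size(k, k, n);
  vec yhat(n), yvar(n);

  vec as = a_filt.col(n - 1);
  mat Psm = Pf.slice(n - 1);
  a_sm.col(n - 1) = as;
  if (want_cov) Ps.slice(n - 1) = Psm;
  yhat(n - 1) = dot(Z, as);
  yvar(n - 1) = as_scalar(Z * Psm * Z.t()) + H;

  bool warned = false;
  for (int t = (int)n - 2; t >= 0; --t) {
    mat Ppn = Pp.slice(t + 1);
    mat TPf = Ts * Pf.slice(t);       // T P_{t|t}
    mat Jt;                           // J = P_{t|t} T' Ppn^{-1}
    bool ok = solve(Jt, Ppn, TPf, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      if (!warned) {
        Rcpp::warning("singular one-step covariance in smoother; ridge-stabilized");
        warned = true;
      }
      Ppn.diag() += 1e-8 * (trace(Ppn) / Ppn.n_rows + 1.0);
      Jt = solve(Ppn, TPf);
    }
    mat J = Jt.t();
    as = a_filt.col(t) + J * (as - a_pred.col(t + 1));
    a_sm.col(t) = as;
    Psm = Pf.slice(t) + J * (Psm - Pp.slice(t + 1)) * J.t();
    Psm = 0.5 * (Psm + Psm.t());
    if (want_cov) Ps.slice(t) = Psm;
    yhat(t) = dot(Z, as);
    yvar(t) = as_scalar(Z * Psm * Z.t()) + H;
    Pf.slice(t) = Psm;                // reuse storage so yvar uses smoothed P
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = ll, Rcpp::Named("a_smooth") = a_sm,
      Rcpp::Named("yhat") = yhat, Rcpp::Named("yvar") = yvar,
      Rcpp::Named("a_filt") = a_filt, Rcpp::Named("a_pred") = a_pred);
  if (want_cov) out["P_smooth"] = Ps;
  return out;
}

// Deterministic simulation given state shocks eta (q x n) and observation
// noise eps (n). State starts at alpha_0 = a_init; alpha_t = T alpha_{t-1} +
// R eta_t; y_t = Z alpha_t + eps_t.
// [[Rcpp::export]]
Rcpp::List cpp_simulate_ssm(const arma::mat& Tm, const arma::rowvec& Z,
                            const arma::mat& Rm, const arma::mat& eta,
                            const arma::vec& eps, const arma::vec& a_init) {
  const uword n = eps.n_elem, k = Tm.n_rows;
  mat alpha(k, n);
  vec yv(n);
  vec a = a_init;
  for (uword t = 0; t < n; ++t) {
    a = Tm * a + Rm * eta.col(t);
    alpha.col(t) = a;
    yv(t) = dot(Z, a) + eps(t);
  }
  return Rcpp::List::create(Rcpp::Named("y") = yv,
                            Rcpp::Named("alpha") = alpha);
}
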