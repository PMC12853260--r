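// Self-tuning Kalman filter for time-varying VAR coefficients estimated
// across repeated trials. The state is the stacked coefficient matrix
// B(t) = [A(1,t) ... A(p,t)] (n x n*p) under a random-walk prior whose
// process noise is absorbed into an adaptation constant c(t) tuned from
// the ratio of current to past across-trial innovation magnitude.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Symmetric inverse via eigendecomposition with a relative eigenvalue
// floor; returns the number of floored eigenvalues through *n_floored.
static mat reg_inv(const mat& M, double rel_floor, int* n_floored) {
  mat Ms = 0.5 * (M + M.t());
  vec ev;
  mat V;
  eig_sym(ev, V, Ms);
  double top = ev.max();
  double floor_v = (top > 0.0) ? top * rel_floor : rel_floor;
  int nf = 0;
  for (uword i = 0; i < ev.n_elem; ++i) {
    if (ev(i) < floor_v) { ev(i) = floor_v; ++nf; }
  }
  if (n_floored) *n_floored += nf;
  return V * diagmat(1.0 / ev) * V.t();
}

// [[Rcpp::export]]
Rcpp::List stok_filter_cpp(const arma::cube& X,  // n x T x R (channels, time, trials)
                           const int p,
                           const double c0,
                           const double c_min,
                           const double c_max,
                           const double ema_alpha,
                           const double p0,
                           const double eig_floor,
                           const double var_floor_rel) {
  const int n = X.n_rows;
  const int T = X.n_cols;
  const int R = X.n_slices;
  const int m = n * p;
  if (T <= p)
    Rcpp::stop("window has %d samples but the model needs more than p = %d", T, p);

  // per-channel data variance, for the innovation-variance floor
  vec chan_var(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    running_stat<double> rs;
    for (int r = 0; r < R; ++r)
      for (int t = 0; t < T; ++t) rs(X(i, t, r));
    chan_var(i) = rs.var();
    if (chan_var(i) <= 0.0) chan_var(i) = 1.0;
  }

  mat B(n, m, fill::zeros);      // stacked coefficients
  mat P = p0 * eye(m, m);        // state covariance (shared across target rows)
  mat S_ema(n, n, fill::zeros);  // smoothed innovation covariance

  const int Tf = T - p;          // fitted time points: t = p .. T-1
  cube B_out(n, m, Tf);
  cube S_out(n, n, Tf);
  vec c_trace(Tf), v_trace(Tf);
  ivec floored(Tf, fill::zeros);

  double v_ema = -1.0;  // unset
  mat Z(R, m), Xt(R, n);

  for (int t = p; t < T; ++t) {
    const int s = t - p;
    for (int r = 0; r < R; ++r) {
      for (int k = 1; k <= p; ++k)
        Z.row(r).subvec((k - 1) * n, k * n - 1) = X.slice(r).col(t - k).t();
      Xt.row(r) = X.slice(r).col(t).t();
    }

    mat E = Xt - Z * B.t();  // across-trial one-step innovations
    double v = accu(E % E) / (double)(R * n);
    if (v_ema < 0.0) v_ema = (v > 0.0) ? v : 1.0;

    double ct;
    if (v_ema > 1e-300)
      ct = c0 * (v / v_ema);
    else
      ct = c_min;
    if (ct < c_min) ct = c_min;
    if (ct > c_max) ct = c_max;

    v_ema = (1.0 - ema_alpha) * v_ema + ema_alpha * v;
    double rhat = (v_ema > 1e-300) ? v_ema : 1e-300;

    int nf = 0;
    mat P_prior = P + ct * (trace(P) / m) * eye(m, m);
    mat P_prior_inv = reg_inv(P_prior, eig_floor, &nf);
    mat M = P_prior_inv + (Z.t() * Z) / rhat;
    mat P_post = reg_inv(M, eig_floor, &nf);
    B = (P_post * (P_prior_inv * B.t() + Z.t() * Xt / rhat)).t();
    P = P_post;

    // innovation covariance: across-trial sample covariance of the prior
    // prediction errors, smoothed by an exponential moving average
    mat S_raw = E.t() * E / (double)std::max(R - 1, 1);
    if (s == 0)
      S_ema = S_raw;
    else
      S_ema = (1.0 - ema_alpha) * S_ema + ema_alpha * S_raw;

    mat S_t = 0.5 * (S_ema + S_ema.t());
    for (int j = 0; j < n; ++j) {
      double fl = var_floor_rel * chan_var(j);
      if (S_t(j, j) < fl) S_t(j, j) = fl;
    }

    B_out.slice(s) = B;
    S_out.slice(s) = S_t;
    c_trace(s) = ct;
    v_trace(s) = v;
    floored(s) = nf;
  }

  return Rcpp::List::create(
      Rcpp::Named("coeffs") = B_out,
      Rcpp::Named("sigma") = S_out,
      Rcpp::Named("c_trace") = c_trace,
      Rcpp::Named("innov_trace") = v_trace,
      Rcpp::Named("floored_eigs") = floored);
}
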