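// Conditional Granger causality from a fitted time-varying VAR.
//
// At each fitted time point the model (A(.,t), Sigma(t)) is treated as
// locally stationary. The full-model residual variance of target j is
// Sigma(t)[j,j]; the reduced-model variance (all channels except the
// source) is obtained from the spectral density of the non-source
// sub-process via Wilson's spectral factorization, so no reduced model is
// refitted on data.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Spectral density of a VAR(p) on N equispaced frequencies over [0, 2*pi).
// Only the first half of the circle is computed; the rest follows from
// S(2*pi - w) = conj(S(w)) for real processes.
static cx_cube var_spectrum(const cube& A, const mat& Sigma, const int N,
                            bool* ok) {
  const int n = Sigma.n_rows;
  const int p = A.n_slices;
  cx_cube S(n, n, N);
  *ok = true;
  const std::complex<double> I_unit(0.0, 1.0);
  const cx_mat Sig_c(Sigma, mat(n, n, fill::zeros));
  cx_mat Aw(n, n), H(n, n);
  for (int k = 0; k <= N / 2; ++k) {
    double w = 2.0 * datum::pi * k / N;
    Aw.eye();
    for (int j = 1; j <= p; ++j) {
      std::complex<double> ph = std::exp(-I_unit * (w * j));
      for (int c = 0; c < n; ++c)
        for (int r = 0; r < n; ++r) Aw(r, c) -= A(r, c, j - 1) * ph;
    }
    if (n == 2) {
      std::complex<double> det = Aw(0, 0) * Aw(1, 1) - Aw(0, 1) * Aw(1, 0);
      if (std::abs(det) < 1e-300) { *ok = false; return S; }
      H(0, 0) = Aw(1, 1) / det;
      H(1, 1) = Aw(0, 0) / det;
      H(0, 1) = -Aw(0, 1) / det;
      H(1, 0) = -Aw(1, 0) / det;
    } else {
      if (!inv(H, Aw)) { *ok = false; return S; }
    }
    S.slice(k) = H * Sig_c * H.t();
    if (k > 0 && k < N - k) S.slice(N - k) = conj(S.slice(k));
  }
  return S;
}

// Causal-part operator of Wilson's algorithm: inverse DFT over frequency,
// keep non-negative lags below N/2 with the zero-lag term halved, DFT back.
static cx_cube plus_operator(const cx_cube& g) {
  const int n = g.n_rows;
  const int N = g.n_slices;
  cx_mat G(N, n * n);
  for (int k = 0; k < N; ++k)
    G.row(k) = vectorise(g.slice(k)).st();
  cx_mat gam = ifft(G);
  gam.row(0) *= 0.5;
  for (int mlag = N / 2; mlag < N; ++mlag) gam.row(mlag).zeros();
  cx_mat Gp = fft(gam);
  cx_cube out(n, n, N);
  for (int k = 0; k < N; ++k)
    out.slice(k) = reshape(Gp.row(k).st(), n, n);
  return out;
}

// Wilson spectral factorization S(w) = psi(w) psi(w)^H with psi causal and
// minimum phase. Returns the implied innovation covariance A0 A0^T where
// A0 is the zero-lag coefficient of psi.
static bool wilson_factor(const cx_cube& S, const int max_iter,
                          const double tol, mat& Sigma_out, int* iters) {
  const int n = S.n_rows;
  const int N = S.n_slices;
  mat S0(n, n, fill::zeros);
  for (int k = 0; k < N; ++k) S0 += real(S.slice(k));
  S0 /= (double)N;
  S0 = 0.5 * (S0 + S0.t());
  mat L;
  if (!chol(L, S0 + 1e-14 * trace(S0) / n * eye(n, n), "lower")) return false;

  cx_cube psi(n, n, N);
  for (int k = 0; k < N; ++k)
    psi.slice(k) = cx_mat(L, mat(n, n, fill::zeros));

  cx_cube g(n, n, N);
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    for (int k = 0; k < N; ++k) {
      cx_mat pk = psi.slice(k);
      cx_mat tmp;
      if (!solve(tmp, pk, S.slice(k))) return false;  // psi^{-1} S
      cx_mat tmp2;
      if (!solve(tmp2, pk, tmp.t())) return false;    // (psi^{-1} (psi^{-1} S)^H)
      g.slice(k) = tmp2.t() + eye<cx_mat>(n, n);      // psi^{-1} S psi^{-H} + I
    }
    cx_cube gp = plus_operator(g);
    double num = 0.0, den = 0.0;
    for (int k = 0; k < N; ++k) {
      cx_mat nw = psi.slice(k) * gp.slice(k);
      num += norm(nw - psi.slice(k), "fro");
      den += norm(psi.slice(k), "fro");
      psi.slice(k) = nw;
    }
    if (num / std::max(den, 1e-300) < tol) { converged = true; ++it; break; }
  }
  if (iters) *iters = it;

  cx_mat A0c(n, n, fill::zeros);
  for (int k = 0; k < N; ++k) A0c += psi.slice(k);
  mat A0 = real(A0c) / (double)N;
  Sigma_out = A0 * A0.t();
  return converged;
}

// [[Rcpp::export]]
Rcpp::List wilson_sf_cpp(const arma::cx_cube& S, const int max_iter,
                         const double tol) {
  mat Sig;
  int iters = 0;
  bool ok = wilson_factor(S, max_iter, tol, Sig, &iters);
  return Rcpp::List::create(Rcpp::Named("sigma") = Sig,
                            Rcpp::Named("converged") = ok,
                            Rcpp::Named("iterations") = iters);
}

// [[Rcpp::export]]
arma::cx_cube var_spectrum_cpp(const arma::cube& A, const arma::mat& Sigma,
                               const int nfreq) {
  bool ok = true;
  cx_cube S = var_spectrum(A, Sigma, 2 * nfreq, &ok);
  if (!ok) Rcpp::stop("VAR operator is singular on the frequency grid");
  return S;
}

// [[Rcpp::export]]
Rcpp::List conditional_gc_cpp(const arma::cube& B,     // n x n*p x T
                              const arma::cube& Sig,   // n x n x T
                              const int p,
                              const int nfreq,
                              const int max_iter,
                              const double tol) {
  const int n = B.n_rows;
  const int T = B.n_slices;
  const int N = 2 * nfreq;

  cube gc(n, n, T);
  gc.fill(datum::nan);
  cube raw(n, n, T);
  raw.fill(datum::nan);
  imat nonconv(n, T, fill::zeros);  // [source, time] flags

  cube A(n, n, p);
  for (int t = 0; t < T; ++t) {
    for (int k = 1; k <= p; ++k)
      A.slice(k - 1) = B.slice(t).cols((k - 1) * n, k * n - 1);

    bool sp_ok = true;
    cx_cube S_full = var_spectrum(A, Sig.slice(t), N, &sp_ok);
    if (!sp_ok) {
      nonconv.col(t).ones();
      continue;
    }

    for (int i = 0; i < n; ++i) {
      uvec idx(n - 1);
      int c = 0;
      for (int j = 0; j < n; ++j)
        if (j != i) idx(c++) = j;

      if (n - 1 == 1) {
        // scalar sub-process: Kolmogorov/Szego formula on the grid
        int j = idx(0);
        double acc = 0.0;
        bool pos = true;
        for (int k = 0; k < N; ++k) {
          double s = std::real(S_full(j, j, k));
          if (s <= 0.0) { pos = false; break; }
          acc += std::log(s);
        }
        if (!pos) { nonconv(i, t) = 1; continue; }
        double sig_red = std::exp(acc / N);
        double r = std::log(sig_red / Sig(j, j, t));
        raw(i, j, t) = r;
        gc(i, j, t) = (r > 0.0) ? r : 0.0;
      } else {
        cx_cube S_sub(n - 1, n - 1, N);
        for (int k = 0; k < N; ++k)
          S_sub.slice(k) = S_full.slice(k).submat(idx, idx);
        mat Sred;
        int iters = 0;
        bool ok = wilson_factor(S_sub, max_iter, tol, Sred, &iters);
        if (!ok) {
          nonconv(i, t) = 1;
          continue;
        }
        for (uword jj = 0; jj < idx.n_elem; ++jj) {
          int j = idx(jj);
          double r = std::log(Sred(jj, jj) / Sig(j, j, t));
          raw(i, j, t) = r;
          gc(i, j, t) = (r > 0.0) ? r : 0.0;
        }
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("gc") = gc,
                            Rcpp::Named("raw") = raw,
                            Rcpp::Named("nonconverged") = nonconv);
}
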