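`%||%` <- function(a, b) if (is.null(a)) b else a

# numerical slack used when mapping continuous windows onto the sample grid
.time_tol <- 1e-9

# ceiling that forgives floating-point droop (2.6/0.13 = 20.0000000004 -> 20)
idx_ceil <- function(x) ceiling(x - 1e-9)

# indices of time axis samples falling in the half-open window [a, b)
window_indices <- function(time_s, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  which(time_s >= window[1] - .time_tol & time_s < window[2] - .time_tol)
}

# companion matrix of a VAR(p) coefficient set (n x n x p)
companion_matrix <- function(A) {
  n <- dim(A)[1]
  p <- dim(A)[3]
  FF <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) FF[seq_len(n), (k - 1) * n + seq_len(n)] <- A[, , k]
  if (p > 1) {
    FF[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <-
      diag(n * (p - 1))
  }
  FF
}

spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

# EMA weight per sample for a half-life expressed in seconds
halflife_alpha <- function(halflife_s, dt) 1 - 2^(-dt / halflife_s)

is_spd <- function(M, tol = 1e-10) {
  if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
  ev <- eigen(0.5 * (M + t(M)), symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev), 1)
}

# stable per-element seed stream kept inside 32-bit range
counter_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(counter)) %% 2147483563) + 1L
}
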