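#' Ground-truth time-varying VAR network
#'
#' Defines the generative model used by [generate_trials()]: a (possibly
#' time-varying) vector autoregression
#' \deqn{x(t) = A(1,t) x(t-1) + \dots + A(p,t) x(t-p) + \epsilon(t)}
#' with innovation covariance `noise_cov`. Coefficient orientation is
#' `coeffs[target, source, lag, time]`, i.e. `coeffs[j, i, k, t]` is the
#' weight of channel `i`'s lag-`k` past on channel `j`.
#'
#' The schedule must be stable at every time index (companion spectral
#' radius < 1) and `noise_cov` must be symmetric positive-definite;
#' violations are rejected at construction with a diagnostic naming the
#' offending time index.
#'
#' @param coeffs numeric array, `n x n x p` (time-invariant) or
#'   `n x n x p x T` (one coefficient set per epoch sample).
#' @param noise_cov `n x n` innovation covariance (default identity).
#' @param labels optional [channel_map()] (or data frame) assigning channels
#'   to ROIs and hemispheres; carried through to generated datasets.
#' @return An object of class `"ground_truth_network"`.
#' @seealso [var_network()] for a convenience constructor,
#'   [generate_trials()], [analytic_gc_stationary()]
#' @export
ground_truth_network <- function(coeffs, noise_cov = NULL, labels = NULL) {
  if (length(dim(coeffs)) == 3) {
    coeffs <- array(coeffs, dim = c(dim(coeffs), 1L))
  }
  stopifnot(length(dim(coeffs)) == 4)
  n <- dim(coeffs)[1]
  if (dim(coeffs)[2] != n) stop("coefficient matrices must be square")
  p <- dim(coeffs)[3]
  n_time <- dim(coeffs)[4]
  if (!all(is.finite(coeffs))) stop("coefficients must be finite")
  noise_cov <- noise_cov %||% diag(n)
  if (!all(dim(noise_cov) == c(n, n)) || !is_spd(noise_cov)) {
    stop("noise_cov must be a symmetric positive-definite ", n, "x", n,
         " matrix")
  }
  # stability at every time index
  for (t in seq_len(n_time)) {
    At <- array(coeffs[, , , t], dim = c(n, n, p))
    rho <- spectral_radius(companion_matrix(At))
    if (rho >= 1) {
      stop(sprintf(
        "unstable coefficient schedule: companion spectral radius %.3f >= 1 at time index %d",
        rho, t))
    }
  }
  structure(
    list(n_channels = n, order = p, n_time = n_time, coeffs = coeffs,
         noise_cov = noise_cov, labels = labels),
    class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(
    "Ground-truth VAR network: %d channels, order %d, %s\n",
    x$n_channels, x$order,
    if (x$n_time == 1) "time-invariant" else
      sprintf("time-varying (%d time indices)", x$n_time)))
  invisible(x)
}

#' Build a VAR network from a coupling table
#'
#' Convenience constructor for [ground_truth_network()]: starts from
#' lag-1 self-couplings (`self` on the diagonal) and adds directed
#' cross-couplings from a table. Each coupling may be restricted to a
#' time-index window, producing a piecewise-constant schedule.
#'
#' @param n number of channels.
#' @param order lag count `p`.
#' @param self lag-1 self-coupling, scalar or length-`n` vector.
#' @param couplings data frame with columns `source`, `target`, `value` and
#'   optionally `lag` (default 1), `from`, `to` (time-index window,
#'   defaults to the whole schedule).
#' @param noise_cov innovation covariance (default identity).
#' @param labels optional channel map.
#' @param n_time schedule length; 1 (default) gives a time-invariant
#'   network.
#' @return A `"ground_truth_network"`.
#' @export
var_network <- function(n, order = 1, self = 0.3, couplings = NULL,
                        noise_cov = NULL, labels = NULL, n_time = 1) {
  coeffs <- array(0, dim = c(n, n, order, n_time))
  coeffs[, , 1, ] <- diag(rep_len(self, n))
  if (!is.null(couplings)) {
    stopifnot(all(c("source", "target", "value") %in% names(couplings)))
    for (r in seq_len(nrow(couplings))) {
      k <- if ("lag" %in% names(couplings)) couplings$lag[r] else 1L
      from <- if ("from" %in% names(couplings)) couplings$from[r] else 1L
      to <- if ("to" %in% names(couplings)) couplings$to[r] else n_time
      coeffs[couplings$target[r], couplings$source[r], k, from:to] <-
        couplings$value[r]
    }
  }
  ground_truth_network(coeffs, noise_cov = noise_cov, labels = labels)
}

#' Simulation scenario configuration
#'
#' Fixes the trial structure of a synthetic dataset: trial count, epoch
#' length, sampling interval, onset position, measurement noise, and the
#' random seed. Defaults emulate a hemodynamic recording epoched around a
#' behavioral onset: a 0.13 s sampling interval and a \[-5, 15) s epoch
#' (154 samples, onset at sample 39).
#'
#' @param n_trials trials per generated dataset (>= 1).
#' @param n_time epoch length in samples.
#' @param dt sampling interval in seconds.
#' @param onset_index sample index corresponding to 0 s.
#' @param measurement_noise_sd i.i.d. Gaussian noise added to each sample
#'   after VAR generation (instrument noise).
#' @param amplitude_sd log-normal sd of a per-trial gain factor modelling
#'   trial-to-trial amplitude variability (0 disables it).
#' @param burn_in samples simulated and discarded before each trial so
#'   trials start near the stationary distribution; default `10 * order`.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(n_trials, n_time = 154, dt = 0.13,
                            onset_index = 39, measurement_noise_sd = 0,
                            amplitude_sd = 0, burn_in = NULL, seed = 1) {
  stopifnot(n_trials >= 1, n_time >= 2, dt > 0,
            onset_index >= 1, onset_index <= n_time,
            measurement_noise_sd >= 0, amplitude_sd >= 0)
  structure(
    list(n_trials = as.integer(n_trials), n_time = as.integer(n_time),
         dt = dt, onset_index = as.integer(onset_index),
         measurement_noise_sd = measurement_noise_sd,
         amplitude_sd = amplitude_sd, burn_in = burn_in,
         seed = as.integer(seed)),
    class = "scenario_config")
}

# core VAR simulator: returns n x n_time x R array (burn-in discarded)
simulate_var_trials <- function(network, config) {
  n <- network$n_channels
  p <- network$order
  Tn <- config$n_time
  R <- config$n_trials
  if (network$n_time != 1 && network$n_time != Tn) {
    stop("network schedule length (", network$n_time,
         ") must be 1 or match n_time (", Tn, ")")
  }
  burn <- config$burn_in %||% (10L * p)
  Lt <- t(chol(network$noise_cov))  # lower factor
  total <- burn + Tn
  x <- array(0, dim = c(n, total, R))
  sched <- function(t) {
    # burn-in uses the first scheduled coefficient set
    if (network$n_time == 1) 1L else max(1L, t - burn)
  }
  for (t in seq_len(total)) {
    eps <- Lt %*% matrix(rnorm(n * R), n, R)
    acc <- eps
    kmax <- min(p, t - 1L)
    if (kmax >= 1) {
      ti <- sched(t)
      for (k in seq_len(kmax)) {
        acc <- acc + network$coeffs[, , k, ti] %*% x[, t - k, ]
      }
    }
    x[, t, ] <- acc
  }
  x <- x[, burn + seq_len(Tn), , drop = FALSE]
  if (config$amplitude_sd > 0) {
    gain <- exp(rnorm(R, sd = config$amplitude_sd))
    x <- sweep(x, 3, gain, `*`)
  }
  if (config$measurement_noise_sd > 0) {
    x <- x + array(rnorm(length(x), sd = config$measurement_noise_sd), dim = dim(x))
  }
  x
}

#' Generate trial-structured signals from a ground-truth network
#'
#' Simulates independent trials of the network's (time-varying) VAR.
#' Each trial is preceded by a discarded burn-in so it starts near the
#' stationary distribution; optional i.i.d. measurement noise and a
#' per-trial amplitude gain are applied afterwards. Output is
#' deterministic given the config seed.
#'
#' @param network a [ground_truth_network()].
#' @param config a [scenario_config()].
#' @param condition optional label (e.g. `"pre"`, `"post"`) attached to the
#'   dataset.
#' @return A [trial_dataset()] (`channels x time x trials`).
#' @export
generate_trials <- function(network, config, condition = NULL) {
  stopifnot(inherits(network, "ground_truth_network"),
            inherits(config, "scenario_config"))
  set.seed(config$seed)
  x <- simulate_var_trials(network, config)
  dimnames(x) <- list(channel_names(network), NULL, NULL)
  trial_dataset(x, dt = config$dt, onset_index = config$onset_index,
                condition = condition, channel_map = network$labels)
}

channel_names <- function(network) {
  if (!is.null(network$labels) && "channel" %in% names(network$labels)) {
    as.character(network$labels$channel)
  } else {
    paste0("ch", seq_len(network$n_channels))
  }
}

#' Generate a pre/post condition pair with a known change map
#'
#' Simulates one dataset from each of two networks sharing the same
#' channel set, and reports which directed couplings changed between
#' them. Coupling strength is the time-mean absolute coefficient; an
#' entry whose strength grew is an `"increase"`, one whose strength
#' shrank a `"decrease"`.
#'
#' @param network_pre,network_post ground-truth networks with identical
#'   channel counts and labels.
#' @param config a [scenario_config()]; the post dataset uses a seed
#'   derived deterministically from `config$seed`.
#' @return A list with elements `pre`, `post` (trial datasets) and
#'   `change_map` (data frame: `source`, `target`, `lag`, `pre`, `post`,
#'   `direction`, `magnitude`).
#' @export
make_condition_pair <- function(network_pre, network_post, config) {
  stopifnot(inherits(network_pre, "ground_truth_network"),
            inherits(network_post, "ground_truth_network"))
  if (network_pre$n_channels != network_post$n_channels) {
    stop("channel counts differ between networks (",
         network_pre$n_channels, " vs ", network_post$n_channels, ")")
  }
  if (!identical(network_pre$labels, network_post$labels)) {
    stop("channel labels differ between networks")
  }
  pre <- generate_trials(network_pre, config, condition = "pre")
  cfg_post <- config
  cfg_post$seed <- counter_seed(config$seed, 1L)
  post <- generate_trials(network_post, cfg_post, condition = "post")

  n <- network_pre$n_channels
  p <- max(network_pre$order, network_post$order)
  strength <- function(net, j, i, k) {
    if (k > net$order) return(0)
    mean(abs(net$coeffs[j, i, k, ]))
  }
  value <- function(net, j, i, k) {
    if (k > net$order) return(0)
    mean(net$coeffs[j, i, k, ])
  }
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(p)) {
    s_pre <- strength(network_pre, j, i, k)
    s_post <- strength(network_post, j, i, k)
    v_pre <- value(network_pre, j, i, k)
    v_post <- value(network_post, j, i, k)
    if (abs(v_post - v_pre) > 1e-12 || abs(s_post - s_pre) > 1e-12) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = i, target = j, lag = k, pre = v_pre, post = v_post,
        direction = if (s_post > s_pre) "increase" else if (s_post < s_pre)
          "decrease" else "change",
        magnitude = s_post - s_pre)
    }
  }
  change_map <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = integer(), target = integer(), lag = integer(),
               pre = numeric(), post = numeric(), direction = character(),
               magnitude = numeric())
  list(pre = pre, post = post, change_map = change_map)
}

#' Closed-form Granger causality for a stationary network
#'
#' Exact conditional Granger causality `GC(source -> target)` implied by a
#' time-invariant ground-truth network, computed from the model's exact
#' autocovariance sequence: the full-model residual variance is the
#' innovation variance of the target; the reduced-model variance comes
#' from solving the Yule-Walker equations of the sub-process that
#' excludes the source channel (a long autoregression approximating its
#' VARMA form). Serves as the analytic oracle for the estimation pipeline.
#'
#' @param network a time-invariant [ground_truth_network()].
#' @param source,target channel indices, `source != target`.
#' @param yw_order order of the reduced autoregression (default
#'   `max(20, 4 * p)`).
#' @return The GC value (non-negative up to numerical tolerance).
#' @export
analytic_gc_stationary <- function(network, source, target, yw_order = NULL) {
  stopifnot(inherits(network, "ground_truth_network"))
  if (network$n_time != 1) {
    stop("analytic GC oracle is defined only for time-invariant networks")
  }
  n <- network$n_channels
  p <- network$order
  stopifnot(source >= 1, source <= n, target >= 1, target <= n,
            source != target)
  A <- array(network$coeffs[, , , 1], dim = c(n, n, p))
  Sigma <- network$noise_cov
  q <- yw_order %||% max(20L, 4L * p)

  # exact autocovariances via the companion-form Lyapunov equation
  FF <- companion_matrix(A)
  np <- n * p
  V <- matrix(0, np, np)
  V[seq_len(n), seq_len(n)] <- Sigma
  G <- matrix(solve(diag(np^2) - FF %x% FF, as.vector(V)), np, np)
  Gam <- vector("list", q + 1L)  # Gam[[h+1]] = Cov(x_t, x_{t-h})
  for (h in 0:(p - 1)) Gam[[h + 1L]] <- G[seq_len(n), h * n + seq_len(n)]
  getG <- function(h) if (h >= 0) Gam[[h + 1L]] else t(Gam[[-h + 1L]])
  if (q >= p) {
    for (h in p:q) {
      acc <- matrix(0, n, n)
      for (k in seq_len(p)) acc <- acc + A[, , k] %*% getG(h - k)
      Gam[[h + 1L]] <- acc
    }
  }

  keep <- setdiff(seq_len(n), source)
  ns <- length(keep)
  Gs <- function(h) getG(h)[keep, keep, drop = FALSE]

  # block-Toeplitz normal equations of the reduced autoregression
  M <- matrix(0, q * ns, q * ns)
  for (k in seq_len(q)) for (h in seq_len(q)) {
    M[(k - 1) * ns + seq_len(ns), (h - 1) * ns + seq_len(ns)] <- Gs(h - k)
  }
  Rm <- matrix(0, ns, q * ns)
  for (h in seq_len(q)) Rm[, (h - 1) * ns + seq_len(ns)] <- Gs(h)
  Bmat <- t(solve(M, t(Rm)))

  Cstack <- matrix(0, q * ns, ns)
  for (k in seq_len(q)) Cstack[(k - 1) * ns + seq_len(ns), ] <- t(Gs(k))
  Sigma_red <- Gs(0) - Bmat %*% Cstack

  jj <- match(target, keep)
  log(Sigma_red[jj, jj] / Sigma[target, target])
}
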