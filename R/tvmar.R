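#' Control parameters for the self-tuning Kalman fit
#'
#' Tuning constants of the trial-batched Kalman estimator behind
#' [tvmar()]. The random-walk process noise of the coefficient model is
#' never estimated explicitly; its effect is absorbed into a per-time
#' adaptation constant
#' `c(t) = clamp(c0 * v(t) / v_ema(t), c_min, c_max)`, where `v(t)` is the
#' mean squared across-trial one-step innovation and `v_ema(t)` its
#' exponential moving average.
#'
#' @param c0 baseline adaptation constant (fraction of the state
#'   covariance injected per step when innovations are at their running
#'   level).
#' @param c_min,c_max bounds on the adaptation constant.
#' @param ema_halflife half-life, in seconds, of the exponential moving
#'   averages used for the innovation magnitude and the innovation
#'   covariance.
#' @param p0 initial state covariance scale (state covariance starts at
#'   `p0 * I`).
#' @param eig_floor relative eigenvalue floor used by the regularized
#'   matrix inversions.
#' @param var_floor floor on the diagonal of the innovation covariance,
#'   relative to each channel's data variance.
#' @return A list of class `"tvmar_control"`.
#' @export
tvmar_control <- function(c0 = 0.1, c_min = 1e-4, c_max = 0.5,
                          ema_halflife = 0.5, p0 = 10,
                          eig_floor = 1e-8, var_floor = 1e-12) {
  stopifnot(c0 > 0, c_min > 0, c_min <= c_max, ema_halflife > 0, p0 > 0,
            eig_floor > 0, var_floor >= 0)
  structure(list(c0 = c0, c_min = c_min, c_max = c_max,
                 ema_halflife = ema_halflife, p0 = p0,
                 eig_floor = eig_floor, var_floor = var_floor),
            class = "tvmar_control")
}

#' Fit a time-varying multivariate autoregressive model across trials
#'
#' Estimates the time-varying VAR
#' \deqn{x(t) = A(1,t) x(t-1) + \dots + A(p,t) x(t-p) + \epsilon(t)}
#' from repeated trials with a self-tuning Kalman filter: the stacked
#' coefficient matrix is the filter state, evolving under a random-walk
#' prior, and all trials at time `t` form the observation batch of one
#' update. The innovation covariance `Sigma(t)` is the across-trial
#' sample covariance of the one-step prediction errors, smoothed by an
#' exponential moving average and variance-floored so downstream
#' log-ratios stay finite.
#'
#' Coefficients are initialized at zero with a diffuse state covariance,
#' so the first seconds of the fitted window act as a burn-in; reporting
#' windows downstream (e.g. \[-2, 10\] s after fitting on \[-5, 10\] s)
#' should exclude it.
#'
#' @param data a [trial_dataset()] with at least 2 trials.
#' @param order AR order `p` (lag count).
#' @param window fit window in seconds relative to onset, half-open
#'   `[window[1], window[2])`; default the whole epoch. If the epoch
#'   extends before the window, up to `p` earlier samples are used as lag
#'   context; otherwise the fitted axis starts `p` samples into the
#'   window.
#' @param control a [tvmar_control()].
#' @return An object of class `"tvmar"` with components `coefficients`
#'   (array `target x source x lag x time`), `sigma`
#'   (`n x n x time` innovation covariance), `time` (seconds), `tuning`
#'   (per-time adaptation diagnostics), and the training data.
#' @seealso [conditional_gc()], [residual_variance()]
#' @export
tvmar <- function(data, order = 15, window = NULL,
                  control = tvmar_control()) {
  stopifnot(inherits(data, "trial_dataset"), order >= 1)
  d <- dim(data$x)
  n <- d[1]
  if (d[3] < 2) stop("at least 2 trials are required")
  tt <- trial_time(data)
  window <- window %||% c(tt[1], tt[length(tt)] + data$dt)
  sel <- window_indices(tt, window)
  if (length(sel) <= order) {
    stop(sprintf("fit window holds %d samples but the model needs more than p = %d",
                 length(sel), order))
  }
  lead <- min(order, sel[1] - 1L)  # lag context available before the window
  ext <- (sel[1] - lead):sel[length(sel)]
  alpha <- halflife_alpha(control$ema_halflife, data$dt)

  res <- stok_filter_cpp(data$x[, ext, , drop = FALSE], as.integer(order),
                         control$c0, control$c_min, control$c_max,
                         alpha, control$p0, control$eig_floor,
                         control$var_floor)

  fit_idx <- ext[-seq_len(order)]
  Tf <- length(fit_idx)
  coefs <- array(0, dim = c(n, n, order, Tf),
                 dimnames = list(dimnames(data$x)[[1]], dimnames(data$x)[[1]],
                                 NULL, NULL))
  for (k in seq_len(order)) {
    coefs[, , k, ] <- res$coeffs[, (k - 1) * n + seq_len(n), , drop = FALSE]
  }
  sig <- res$sigma
  dimnames(sig) <- list(dimnames(data$x)[[1]], dimnames(data$x)[[1]], NULL)

  structure(
    list(coefficients = coefs, sigma = sig, time = tt[fit_idx],
         order = as.integer(order), dt = data$dt,
         channels = dimnames(data$x)[[1]], n_trials = d[3],
         window = window, control = control,
         tuning = data.frame(time = tt[fit_idx], c = as.numeric(res$c_trace),
                             innovation = as.numeric(res$innov_trace),
                             floored_eigs = as.integer(res$floored_eigs)),
         data = data, call = match.call()),
    class = "tvmar")
}

#' @export
print.tvmar <- function(x, ...) {
  cat(sprintf(
    "Time-varying VAR fit: %d channels, order %d, %d trials\n",
    length(x$channels), x$order, x$n_trials))
  cat(sprintf("  fitted window: [%.2f, %.2f] s (%d time points, dt = %g s)\n",
              min(x$time), max(x$time), length(x$time), x$dt))
  invisible(x)
}

#' @export
summary.tvmar <- function(object, ...) {
  Tf <- length(object$time)
  s_diag <- t(apply(object$sigma, 3, diag))
  out <- list(
    n = length(object$channels), order = object$order,
    n_trials = object$n_trials, time_range = range(object$time),
    n_time = Tf,
    mean_abs_coef_final = mean(abs(object$coefficients[, , , Tf])),
    innovation_var = colMeans(s_diag),
    adaptation = range(object$tuning$c),
    floored_updates = sum(object$tuning$floored_eigs > 0))
  class(out) <- "summary.tvmar"
  out
}

#' @export
print.summary.tvmar <- function(x, ...) {
  cat(sprintf("tvMAR fit: %d channels, order %d, %d trials, %d time points in [%.2f, %.2f] s\n",
              x$n, x$order, x$n_trials, x$n_time, x$time_range[1], x$time_range[2]))
  cat(sprintf("  mean |coefficient| at final time: %.4f\n", x$mean_abs_coef_final))
  cat(sprintf("  adaptation constant range: [%.2g, %.2g]\n",
              x$adaptation[1], x$adaptation[2]))
  cat(sprintf("  mean innovation variance per channel: %s\n",
              paste(sprintf("%.3g", x$innovation_var), collapse = ", ")))
  cat(sprintf("  updates with floored eigenvalues: %d\n", x$floored_updates))
  invisible(x)
}

#' @export
coef.tvmar <- function(object, ...) object$coefficients

#' Innovation covariance series of a fit
#' @param fit a [tvmar()] fit.
#' @return Array `n x n x time`.
#' @export
innovation_cov <- function(fit) {
  stopifnot(inherits(fit, "tvmar"))
  fit$sigma
}

#' @export
sigma.tvmar <- function(object, ...) {
  out <- sqrt(t(apply(object$sigma, 3, diag)))
  colnames(out) <- object$channels
  out
}

#' Full-model residual variance of a target channel
#'
#' The `(target, target)` diagonal entry of the fitted innovation
#' covariance at one fitted time point: the one-step prediction error
#' variance of the target given the past of all channels. Strictly
#' positive by the variance floor.
#'
#' @param fit a [tvmar()] fit.
#' @param target channel index or name.
#' @param t time index into `fit$time`.
#' @return A positive scalar.
#' @export
residual_variance <- function(fit, target, t) {
  stopifnot(inherits(fit, "tvmar"))
  if (is.character(target)) target <- match(target, fit$channels)
  stopifnot(!is.na(target), target >= 1, target <= length(fit$channels))
  if (t < 1 || t > length(fit$time)) {
    stop("time index ", t, " outside the fitted window (1..",
         length(fit$time), ")")
  }
  fit$sigma[target, target, t]
}

# one-step predictions at the fitted time points for a dataset
tvmar_predict_array <- function(fit, data) {
  tt <- trial_time(data)
  fidx <- vapply(fit$time, function(s) which.min(abs(tt - s)), integer(1))
  if (max(abs(tt[fidx] - fit$time)) > 1e-6) {
    stop("newdata time axis does not cover the fitted window")
  }
  n <- length(fit$channels)
  R <- dim(data$x)[3]
  p <- fit$order
  pred <- array(NA_real_, dim = c(n, length(fidx), R))
  for (s in seq_along(fidx)) {
    t0 <- fidx[s]
    if (t0 - p < 1) stop("not enough lag context in newdata")
    acc <- matrix(0, n, R)
    for (k in seq_len(p)) {
      acc <- acc + fit$coefficients[, , k, s] %*% data$x[, t0 - k, ]
    }
    pred[, s, ] <- acc
  }
  pred
}

#' @export
predict.tvmar <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data
  stopifnot(inherits(newdata, "trial_dataset"))
  tvmar_predict_array(object, newdata)
}

#' @export
residuals.tvmar <- function(object, ...) {
  pred <- tvmar_predict_array(object, object$data)
  tt <- trial_time(object$data)
  fidx <- vapply(object$time, function(s) which.min(abs(tt - s)), integer(1))
  object$data$x[, fidx, , drop = FALSE] - pred
}

#' @export
simulate.tvmar <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$channels)
  p <- object$order
  Tf <- length(object$time)
  for (s in seq_len(Tf)) {
    rho <- spectral_radius(companion_matrix(
      array(object$coefficients[, , , s], dim = c(n, n, p))))
    if (rho >= 1) {
      stop(sprintf("fitted coefficients are unstable at time index %d (spectral radius %.3f); cannot simulate",
                   s, rho))
    }
  }
  burn <- 10L * p
  x <- array(0, dim = c(n, burn + Tf, nsim))
  chol_t <- lapply(seq_len(Tf), function(s) t(chol(0.5 * (object$sigma[, , s] + t(object$sigma[, , s])))))
  for (t in seq_len(burn + Tf)) {
    s <- max(1L, t - burn)
    eps <- chol_t[[s]] %*% matrix(rnorm(n * nsim), n, nsim)
    acc <- eps
    kmax <- min(p, t - 1L)
    if (kmax >= 1) {
      for (k in seq_len(kmax)) {
        acc <- acc + object$coefficients[, , k, s] %*% x[, t - k, ]
      }
    }
    x[, t, ] <- acc
  }
  x <- x[, burn + seq_len(Tf), , drop = FALSE]
  dimnames(x) <- list(object$channels, NULL, NULL)
  onset <- which.min(abs(object$time))
  trial_dataset(x, dt = object$dt, onset_index = onset,
                condition = "simulated")
}

#' @export
plot.tvmar <- function(x, lag = 1, ...) {
  n <- length(x$channels)
  Tf <- length(x$time)
  traces <- NULL
  labs <- character()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    traces <- cbind(traces, x$coefficients[j, i, lag, ])
    labs <- c(labs, paste0(x$channels[i], "->", x$channels[j]))
  }
  graphics::matplot(x$time, traces, type = "l", lty = 1,
                    xlab = "time (s)", ylab = sprintf("lag-%d coefficient", lag),
                    main = "Cross-coupling coefficient trajectories", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
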