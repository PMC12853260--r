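#' Number of ordered channel pairs
#'
#' Directed connections among `n` channels: all ordered pairs `(i, j)`
#' with `i != j`, i.e. `n * (n - 1)`.
#'
#' @param n channel count, `n >= 2`.
#' @return An integer.
#' @examples
#' count_ordered_pairs(27)  # 702
#' count_ordered_pairs(30)  # 870
#' @export
count_ordered_pairs <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n != round(n) || n < 2) {
    stop("n must be a single integer >= 2")
  }
  as.integer(n) * (as.integer(n) - 1L)
}

#' Time-varying conditional Granger causality from a fitted model
#'
#' For every ordered channel pair `(i, j)` and fitted time point `t`,
#' computes `GC(i -> j, t) = ln(sigma_{j\\i}(t) / sigma_j(t))`: the
#' log-ratio of the reduced-model residual variance of the target (all
#' channels except the source) to the full-model residual variance.
#'
#' The default `"efficient"` method never refits on data: at each time
#' point the fitted model is treated as locally stationary, its spectral
#' density is evaluated on a frequency grid, and the reduced innovation
#' variance is obtained by Wilson spectral factorization of the
#' non-source sub-spectrum (the Kolmogorov formula when a single channel
#' remains). The `"refit"` method re-estimates a reduced model on the
#' data for every source and is the slow definitional reference.
#'
#' Values failing non-negativity by numerical error are clipped to 0;
#' the pre-clip values and the clipped fraction are kept in
#' `diagnostics`. Time points where the factorization does not converge
#' are recomputed through the reduced-refit route (when
#' `fallback = TRUE`), never silently zeroed.
#'
#' @param fit a [tvmar()] fit.
#' @param method `"efficient"` (spectral reduction) or `"refit"`
#'   (reduced-model re-estimation).
#' @param nfreq frequency-grid points up to Nyquist (default 64).
#' @param max_iter,tol Wilson factorization iteration cap and relative
#'   convergence tolerance.
#' @param fallback fill non-converged time points via the refit route.
#' @return An object of class `"gc_tensor"`: `gc` is a
#'   `source x target x time` array (diagonal `NA`), plus the time axis,
#'   channel names, method tag and diagnostics.
#' @seealso [conditional_gc_reduced_refit()], [delta_gc()]
#' @export
conditional_gc <- function(fit, method = c("efficient", "refit"),
                           nfreq = 64, max_iter = 100, tol = 1e-8,
                           fallback = TRUE) {
  stopifnot(inherits(fit, "tvmar"))
  method <- match.arg(method)
  n <- length(fit$channels)
  if (n < 2) stop("conditional GC needs at least 2 channels")
  p <- fit$order
  Tf <- length(fit$time)

  if (method == "efficient") {
    B <- array(0, dim = c(n, n * p, Tf))
    for (k in seq_len(p)) {
      B[, (k - 1) * n + seq_len(n), ] <- fit$coefficients[, , k, ]
    }
    res <- conditional_gc_cpp(B, fit$sigma, as.integer(p),
                              as.integer(nfreq), as.integer(max_iter), tol)
    gc_arr <- res$gc
    raw <- res$raw
    nonconv <- res$nonconverged  # n_sources x Tf
    n_fallback <- 0L
    if (any(nonconv > 0) && fallback) {
      for (i in which(rowSums(nonconv) > 0)) {
        bad_t <- which(nonconv[i, ] > 0)
        ref <- gc_refit_source(fit, i)
        for (j in setdiff(seq_len(n), i)) {
          gc_arr[i, j, bad_t] <- pmax(ref[bad_t, match(j, setdiff(seq_len(n), i))], 0)
          raw[i, j, bad_t] <- ref[bad_t, match(j, setdiff(seq_len(n), i))]
        }
        n_fallback <- n_fallback + length(bad_t)
      }
    }
  } else {
    gc_arr <- array(NA_real_, dim = c(n, n, Tf))
    raw <- array(NA_real_, dim = c(n, n, Tf))
    nonconv <- matrix(0L, n, Tf)
    n_fallback <- 0L
    for (i in seq_len(n)) {
      ref <- gc_refit_source(fit, i)
      others <- setdiff(seq_len(n), i)
      for (jj in seq_along(others)) {
        raw[i, others[jj], ] <- ref[, jj]
        gc_arr[i, others[jj], ] <- pmax(ref[, jj], 0)
      }
    }
  }

  off <- !diag(n)
  raw_off <- raw[rep(off, Tf)]
  clipped <- mean(raw_off < 0, na.rm = TRUE)
  dimnames(gc_arr) <- list(fit$channels, fit$channels, NULL)
  structure(
    list(gc = gc_arr, raw = raw, time = fit$time, channels = fit$channels,
         method = method,
         diagnostics = list(clipped_fraction = clipped,
                            nonconverged = sum(nonconv),
                            fallback_points = n_fallback)),
    class = "gc_tensor")
}

# reduced-refit GC series for one source: Tf x (n-1) matrix of
# ln(sigma_red_j(t) / sigma_full_j(t)) over targets j != source
gc_refit_source <- function(fit, source) {
  data <- fit$data
  keep <- setdiff(seq_along(fit$channels), source)
  red_data <- trial_dataset(data$x[keep, , , drop = FALSE], dt = data$dt,
                            onset_index = data$onset_index,
                            condition = data$condition, validate = FALSE)
  red_fit <- tvmar(red_data, order = fit$order, window = fit$window,
                   control = fit$control)
  Tf <- length(fit$time)
  out <- matrix(NA_real_, Tf, length(keep))
  for (jj in seq_along(keep)) {
    j <- keep[jj]
    out[, jj] <- log(red_fit$sigma[jj, jj, ] / fit$sigma[j, j, ])
  }
  out
}

#' Conditional GC by explicit reduced-model refit
#'
#' The definitional route: refits the time-varying model on all channels
#' except the source and returns `ln(sigma_reduced(t) / sigma_full(t))`
#' for the requested target(s). About `n` times slower than the spectral
#' path of [conditional_gc()]; serves as its correctness reference.
#'
#' @param data a [trial_dataset()].
#' @param source source channel index or name.
#' @param target target channel index/name, or `NULL` for all non-source
#'   channels.
#' @param order,window,control as in [tvmar()].
#' @param full_fit optionally a precomputed full-model fit on the same
#'   data/options, to avoid refitting it.
#' @return A matrix `time x targets` (or a vector when a single target is
#'   requested) of unclipped GC values, with the fitted time axis as the
#'   `"time"` attribute.
#' @export
conditional_gc_reduced_refit <- function(data, source, target = NULL,
                                         order = 15, window = NULL,
                                         control = tvmar_control(),
                                         full_fit = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  fit <- full_fit %||% tvmar(data, order = order, window = window,
                             control = control)
  chans <- fit$channels
  if (is.character(source)) source <- match(source, chans)
  ref <- gc_refit_source(fit, source)
  others <- setdiff(seq_along(chans), source)
  colnames(ref) <- chans[others]
  attr(ref, "time") <- fit$time
  if (!is.null(target)) {
    if (is.character(target)) target <- match(target, chans)
    if (target == source) stop("target must differ from source")
    out <- ref[, match(target, others)]
    attr(out, "time") <- fit$time
    return(out)
  }
  ref
}

#' @export
print.gc_tensor <- function(x, ...) {
  n <- length(x$channels)
  cat(sprintf(
    "GC tensor (%s): %d ordered pairs x %d time points in [%.2f, %.2f] s\n",
    x$method, count_ordered_pairs(n), length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  clipped fraction: %.3f; non-converged points: %d\n",
              x$diagnostics$clipped_fraction, x$diagnostics$nonconverged))
  invisible(x)
}

#' @export
as.data.frame.gc_tensor <- function(x, ...) {
  n <- length(x$channels)
  grid <- expand.grid(source = seq_len(n), target = seq_len(n),
                      t = seq_along(x$time))
  grid <- grid[grid$source != grid$target, ]
  data.frame(source = x$channels[grid$source],
             target = x$channels[grid$target],
             time_s = x$time[grid$t],
             gc = x$gc[cbind(grid$source, grid$target, grid$t)])
}

#' @export
plot.gc_tensor <- function(x, ...) {
  n <- length(x$channels)
  avg <- apply(x$gc, c(1, 2), mean, na.rm = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(avg)[, n:1],
                  xlab = "target", ylab = "source", axes = FALSE,
                  main = "Time-averaged conditional GC", ...)
  graphics::axis(1, at = seq_len(n), labels = x$channels)
  graphics::axis(2, at = seq_len(n), labels = rev(x$channels))
  invisible(x)
}
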