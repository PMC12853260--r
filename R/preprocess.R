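#' Continuous multichannel recording
#'
#' A `channels x samples` matrix with its sampling interval, trial onset
#' sample indices, and optional pathway identifiers marking the paired
#' bidirectional optical pathways of each measurement channel.
#'
#' @param x numeric matrix, `channels x samples`.
#' @param dt sampling interval in seconds.
#' @param onsets trial-onset sample indices, strictly increasing.
#' @param pathway optional character/integer vector (one per row):
#'   rows sharing a pathway id are the two directions of one channel and
#'   are combined by [average_pathways()].
#' @return An object of class `"continuous_recording"`.
#' @export
continuous_recording <- function(x, dt, onsets = integer(), pathway = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  stopifnot(is.matrix(x), dt > 0)
  if (!all(is.finite(x))) stop("recording contains non-finite values")
  onsets <- as.integer(onsets)
  if (length(onsets)) {
    if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing")
    if (min(onsets) < 1 || max(onsets) > ncol(x)) {
      stop("onsets must lie within the recording")
    }
  }
  if (!is.null(pathway)) stopifnot(length(pathway) == nrow(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("ch", seq_len(nrow(x)))
  structure(list(x = x, dt = dt, onsets = onsets, pathway = pathway),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("Continuous recording: %d channels x %d samples (dt = %g s, %d onsets)\n",
              nrow(x$x), ncol(x$x), x$dt, length(x$onsets)))
  invisible(x)
}

# forward-backward IIR pass with odd-reflection padding of `pad` samples
filtfilt_refl <- function(v, b, a, pad) {
  n <- length(v)
  xp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies an `order`-th order Butterworth bandpass forward and backward
#' (zero phase; effective magnitude response of order `2 * order`) to each
#' channel, then subtracts a constant per channel so the first sample is
#' exactly zero.
#'
#' Edge transients are handled by odd-reflection padding scaled to the
#' slowest filter transient (about 20 time constants of the low corner,
#' capped at the record length), so the forward-backward cascade is
#' reversal-symmetric to high precision and a constant input maps to an
#' (essentially) zero output.
#'
#' @param recording a [continuous_recording()].
#' @param low,high band edges in Hz, `0 < low < high < ` Nyquist.
#' @param order bandpass filter order (even; default 4).
#' @param pad padding length in samples; default
#'   `min(n - 1, max(3 * order, ceil(5 / (low * dt))))`.
#' @return A filtered [continuous_recording()].
#' @export
bandpass_filter <- function(recording, low = 0.02, high = 0.3, order = 4,
                            pad = NULL) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- 1 / recording$dt
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                 low, high, fs / 2))
  }
  if (order < 2 || order %% 2 != 0) stop("order must be a positive even integer")
  nsamp <- ncol(recording$x)
  if (nsamp <= 3L * order + 1L) {
    stop("recording too short for stable filtering (needs more than ",
         3L * order + 1L, " samples)")
  }
  pad <- pad %||% min(nsamp - 1L,
                      max(3L * order, ceiling(5 / (low * recording$dt))))
  pad <- as.integer(pad)
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  y <- t(apply(recording$x, 1, filtfilt_refl, b = bf$b, a = bf$a, pad = pad))
  y <- y - y[, 1]  # initial value to zero, per channel
  out <- recording
  out$x <- y
  rownames(out$x) <- rownames(recording$x)
  out
}

#' Average the two bidirectional-pathway signals of one channel
#'
#' @param path_a,path_b numeric vectors of equal length (the two optical
#'   pathway signals of a channel).
#' @return Their element-wise mean.
#' @export
average_bidirectional <- function(path_a, path_b) {
  if (length(path_a) != length(path_b)) {
    stop("pathway signals differ in length (", length(path_a), " vs ",
         length(path_b), ")")
  }
  (path_a + path_b) / 2
}

#' Collapse bidirectional pathways of a recording
#'
#' Averages every pair (or group) of rows sharing a pathway identifier,
#' yielding one channel per pathway in order of first appearance.
#'
#' @param recording a [continuous_recording()] with `pathway` set.
#' @return A [continuous_recording()] with one row per pathway id.
#' @export
average_pathways <- function(recording) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (is.null(recording$pathway)) stop("recording has no pathway identifiers")
  ids <- unique(recording$pathway)
  y <- t(vapply(ids, function(id) {
    colMeans(recording$x[recording$pathway == id, , drop = FALSE])
  }, numeric(ncol(recording$x))))
  rownames(y) <- as.character(ids)
  continuous_recording(y, dt = recording$dt, onsets = recording$onsets)
}

#' Epoch a recording around trial onsets and baseline-correct
#'
#' Extracts the half-open window `[window[1], window[2])` s around each
#' onset (sample `k` belongs to the epoch iff
#' `window[1] <= t(k) - t(onset) < window[2]`) and subtracts, per trial
#' and channel, the mean over the half-open baseline window. Trials whose
#' window leaves the recording are dropped with a warning.
#'
#' @param recording a [continuous_recording()] with onsets.
#' @param window epoch window in seconds, default `c(-5, 15)`.
#' @param baseline baseline window in seconds, default `c(-5, 0)`.
#' @param condition,channel_map passed to the resulting [trial_dataset()].
#' @return A [trial_dataset()] whose baseline-window mean is 0 per trial
#'   and channel.
#' @export
epoch_and_baseline <- function(recording, window = c(-5, 15),
                               baseline = c(-5, 0), condition = NULL,
                               channel_map = NULL) {
  stopifnot(inherits(recording, "continuous_recording"),
            length(window) == 2, window[1] < window[2],
            length(baseline) == 2, baseline[1] < baseline[2])
  if (!length(recording$onsets)) stop("recording has no trial onsets")
  dt <- recording$dt
  offsets <- idx_ceil(window[1] / dt):(idx_ceil(window[2] / dt) - 1L)
  b_off <- idx_ceil(baseline[1] / dt):(idx_ceil(baseline[2] / dt) - 1L)
  if (!all(b_off %in% offsets)) stop("baseline window must lie inside the epoch window")
  b_pos <- match(b_off, offsets)

  n <- nrow(recording$x)
  nsamp <- ncol(recording$x)
  keep <- list()
  for (i in seq_along(recording$onsets)) {
    idx <- recording$onsets[i] + offsets
    if (min(idx) < 1 || max(idx) > nsamp) {
      warning(sprintf("trial %d dropped: epoch window extends beyond the recording", i))
      next
    }
    ep <- recording$x[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, b_pos, drop = FALSE])
    keep[[length(keep) + 1L]] <- ep
  }
  if (!length(keep)) stop("no trial admits the full epoch window")
  x <- array(unlist(keep), dim = c(n, length(offsets), length(keep)),
             dimnames = list(rownames(recording$x), NULL, NULL))
  trial_dataset(x, dt = dt, onset_index = 1L - offsets[1],
                condition = condition, channel_map = channel_map)
}
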