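#' Trial-epoched multichannel dataset
#'
#' The container consumed by [tvmar()]: a `channels x time x trials`
#' array with its sampling interval, the sample index of the trial onset
#' (0 s), an optional condition label and an optional channel map.
#'
#' @param x numeric array, `channels x time x trials`.
#' @param dt sampling interval in seconds.
#' @param onset_index sample index corresponding to 0 s.
#' @param condition optional label, e.g. `"pre"` or `"post"`.
#' @param channel_map optional [channel_map()].
#' @param validate skip checks (internal fast path).
#' @return An object of class `"trial_dataset"`.
#' @export
trial_dataset <- function(x, dt, onset_index, condition = NULL,
                          channel_map = NULL, validate = TRUE) {
  if (validate) {
    stopifnot(is.array(x), length(dim(x)) == 3, dt > 0,
              onset_index >= 1, onset_index <= dim(x)[2])
    if (!all(is.finite(x))) stop("dataset contains non-finite values")
  }
  if (is.null(dimnames(x)[[1]])) {
    dimnames(x) <- list(paste0("ch", seq_len(dim(x)[1])),
                        NULL, NULL)
  }
  structure(
    list(x = x, dt = dt, onset_index = as.integer(onset_index),
         condition = condition, channel_map = channel_map),
    class = "trial_dataset")
}

#' Time axis of a trial dataset (seconds relative to onset)
#' @param data a [trial_dataset()].
#' @return Numeric vector of length `dim(data$x)[2]`.
#' @export
trial_time <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  (seq_len(dim(data$x)[2]) - data$onset_index) * data$dt
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$x)
  tt <- trial_time(x)
  cat(sprintf(
    "Trial dataset: %d channels x %d samples x %d trials (dt = %g s, t in [%.2f, %.2f] s)%s\n",
    d[1], d[2], d[3], x$dt, min(tt), max(tt),
    if (is.null(x$condition)) "" else paste0(", condition: ", x$condition)))
  invisible(x)
}

#' @export
as.data.frame.trial_dataset <- function(x, ...) {
  d <- dim(x$x)
  data.frame(
    condition = if (is.null(x$condition)) NA_character_ else x$condition,
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(dimnames(x$x)[[1]], times = d[2] * d[3]),
    sample = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_s = rep(rep(trial_time(x), each = d[1]), times = d[3]),
    value = as.vector(x$x))
}

#' Write / read a trial dataset as a long-format delimited table
#'
#' Plain-text round trip: one row per (trial, channel, sample) with the
#' sampling interval and onset index carried as `#`-prefixed header
#' lines.
#'
#' @param data a [trial_dataset()].
#' @param path file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a [trial_dataset()].
#' @export
write_trials <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dt: %.17g", data$dt),
               sprintf("# onset_index: %d", data$onset_index),
               sprintf("# condition: %s", data$condition %||% "NA")), con)
  df <- as.data.frame(data)[, c("condition", "trial", "channel", "sample", "value")]
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  hdr <- readLines(path, n = 3)
  get <- function(key) sub(paste0("# ", key, ": "), "", grep(key, hdr, value = TRUE))
  dt <- as.numeric(get("dt"))
  onset <- as.integer(get("onset_index"))
  condition <- get("condition")
  if (identical(condition, "NA")) condition <- NULL
  df <- read.csv(path, comment.char = "#")
  channels <- unique(df$channel)
  n <- length(channels)
  n_time <- max(df$sample)
  n_trials <- max(df$trial)
  x <- array(NA_real_, dim = c(n, n_time, n_trials),
             dimnames = list(channels, NULL, NULL))
  x[cbind(match(df$channel, channels), df$sample, df$trial)] <- df$value
  trial_dataset(x, dt = dt, onset_index = onset, condition = condition)
}
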