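#' Trial-label permutation test for pre/post GC-change statistics
#'
#' Builds surrogate datasets by randomly permuting the pre/post labels
#' across the pooled trials (group sizes preserved), recomputes the
#' statistic for each surrogate — a full refit of both condition models
#' when the statistic contains one — and reports, per scalar component,
#' the two-sided permutation p-value
#' `p = #\{|surrogate| >= |observed|\} / B`.
#'
#' When pre/post pairs exist for several hand conditions, call this once
#' per hand so labels are shuffled within each hand condition.
#' Surrogates draw from a counter-based seed sequence, so results are
#' reproducible and independent of evaluation order; a surrogate whose
#' statistic fails is retried on the next seed stream and counted in the
#' diagnostics.
#'
#' @param pre,post [trial_dataset()]s sharing channels and epoch axes.
#' @param statistic `function(pre, post)` returning a named numeric
#'   vector of scalar quantities (any pipeline composition, e.g.
#'   [gc_change_statistic()]).
#' @param B number of surrogates (full-scale default: 1000).
#' @param seed integer seed driving the surrogate streams.
#' @param correction use the conservative `(r + 1) / (B + 1)` estimator
#'   instead of `r/B` (off by default; the plain `r/B` estimator admits
#'   p = 0).
#' @return An object of class `"permutation_result"`: `table` (data
#'   frame `id`, `observed`, `p`), the `B x K` surrogate matrix, and
#'   diagnostics.
#' @seealso [bh_fdr()]
#' @export
permutation_test <- function(pre, post, statistic, B = 1000, seed = 1,
                             correction = FALSE) {
  stopifnot(inherits(pre, "trial_dataset"), inherits(post, "trial_dataset"))
  if (B < 1) stop("B must be at least 1")
  if (dim(pre$x)[1] != dim(post$x)[1] || dim(pre$x)[2] != dim(post$x)[2]) {
    stop("pre and post datasets must share channels and epoch axes")
  }
  obs <- statistic(pre, post)
  if (is.null(names(obs))) names(obs) <- paste0("stat", seq_along(obs))
  K <- length(obs)

  pooled <- array(c(pre$x, post$x),
                  dim = c(dim(pre$x)[1], dim(pre$x)[2],
                          dim(pre$x)[3] + dim(post$x)[3]))
  dimnames(pooled) <- list(dimnames(pre$x)[[1]], NULL, NULL)
  n1 <- dim(pre$x)[3]
  ntot <- dim(pooled)[3]

  surr <- matrix(NA_real_, B, K)
  retries <- 0L
  for (b in seq_len(B)) {
    for (attempt in 0:9) {
      set.seed(counter_seed(seed, b + attempt * (B + 1L)))
      perm <- sample.int(ntot)
      spre <- trial_dataset(pooled[, , perm[seq_len(n1)], drop = FALSE],
                            dt = pre$dt, onset_index = pre$onset_index,
                            validate = FALSE)
      spost <- trial_dataset(pooled[, , perm[(n1 + 1):ntot], drop = FALSE],
                             dt = pre$dt, onset_index = pre$onset_index,
                             validate = FALSE)
      val <- tryCatch(statistic(spre, spost), error = function(e) NULL)
      if (!is.null(val)) break
      retries <- retries + 1L
    }
    if (is.null(val)) stop("statistic failed on surrogate ", b,
                           " after repeated retries")
    surr[b, ] <- val
  }

  r <- colSums(abs(surr) >= matrix(abs(obs), B, K, byrow = TRUE))
  p <- if (correction) (r + 1) / (B + 1) else r / B
  structure(
    list(table = data.frame(id = names(obs), observed = as.numeric(obs),
                            p = p, row.names = NULL),
         surrogates = surr, B = B, seed = seed, retries = retries,
         correction = correction),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: %d statistics, B = %d surrogates (%s estimator)\n",
              nrow(x$table), x$B,
              if (x$correction) "(r+1)/(B+1)" else "r/B"))
  print(head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Plain step-up rule: sort the p-values ascending, find the largest `k`
#' with `p_(k) <= q * k / m`, and flag every p-value `<= p_(k)`; nothing
#' is flagged when no such `k` exists. Applied collectively to all
#' scalar quantities of one analysis (one family per analysis).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param q FDR level in `(0, 1)` (default 0.1).
#' @return Logical vector of significance flags, same order as input.
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(p_values)
  if (!m) return(logical())
  ps <- sort(p_values)
  ok <- which(ps <= q * seq_len(m) / m)
  if (!length(ok)) return(rep(FALSE, m))
  p_values <= ps[max(ok)]
}

#' Build a GC-change statistic for permutation testing
#'
#' Returns a `function(pre, post)` that fits the time-varying model to
#' each dataset, computes conditional GC, and integrates the channel-level
#' GC change (`post - pre`, positive and negative parts summed
#' separately) over a reporting window, yielding one scalar per ordered
#' channel pair and sign. Tuning is re-run per dataset, so surrogates are
#' re-tuned exactly like the observed data.
#'
#' @param order AR order passed to [tvmar()].
#' @param fit_window fit window in seconds (default the whole epoch).
#' @param report_window integration window in seconds (default the
#'   fitted axis).
#' @param control a [tvmar_control()].
#' @param pairs optional 2-column matrix of (source, target) channel
#'   indices to restrict the statistic to.
#' @param parts `"both"`, `"positive"` or `"negative"`: which signed
#'   integrated changes to return.
#' @param nfreq frequency-grid size for [conditional_gc()].
#' @return A statistic function usable with [permutation_test()].
#' @export
gc_change_statistic <- function(order, fit_window = NULL,
                                report_window = NULL,
                                control = tvmar_control(), pairs = NULL,
                                parts = c("both", "positive", "negative"),
                                nfreq = 64) {
  parts <- match.arg(parts)
  function(pre, post) {
    fit_pre <- tvmar(pre, order = order, window = fit_window,
                     control = control)
    fit_post <- tvmar(post, order = order, window = fit_window,
                      control = control)
    g_pre <- conditional_gc(fit_pre, nfreq = nfreq)
    g_post <- conditional_gc(fit_post, nfreq = nfreq)
    d <- delta_gc(g_pre, g_post)
    idx <- if (is.null(report_window)) seq_along(d$time) else
      gc_window_indices(d$time, report_window)
    n <- length(d$channels)
    pr <- pairs
    if (is.null(pr)) {
      pr <- expand.grid(source = seq_len(n), target = seq_len(n))
      pr <- as.matrix(pr[pr$source != pr$target, ])
    }
    out <- numeric(0)
    for (r in seq_len(nrow(pr))) {
      v <- d$delta[pr[r, 1], pr[r, 2], idx]
      nm <- paste0(d$channels[pr[r, 1]], "->", d$channels[pr[r, 2]])
      if (parts %in% c("both", "positive")) {
        out[paste0(nm, "+")] <- sum(pmax(v, 0))
      }
      if (parts %in% c("both", "negative")) {
        out[paste0(nm, "-")] <- sum(pmin(v, 0))
      }
    }
    out
  }
}
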