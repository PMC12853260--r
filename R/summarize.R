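#' Channel-to-ROI map
#'
#' Assigns each channel to at most one region of interest (ROI) and each
#' ROI to a hemisphere. Channels labelled `"unassigned"` are excluded
#' from region-level summaries but still take part in the conditional GC
#' computation (they condition the pairwise index, attenuating their
#' confounding influence). Medially located ROIs (e.g. the SMA) carry the
#' `"medial"` tag and are counted in both hemispheres by
#' [hemisphere_means()].
#'
#' @param channel channel ids (coerced to character).
#' @param roi ROI label per channel, `"unassigned"` for unmapped
#'   channels.
#' @param hemisphere hemisphere tag per channel: `"ipsilesional"`,
#'   `"contralesional"`, `"medial"`, or `NA` for unassigned channels.
#'   Must be constant within each ROI.
#' @param seed logical flag per channel marking seed channels for
#'   [seed_channel_view()].
#' @return A data frame of class `"channel_map"`.
#' @export
channel_map <- function(channel, roi, hemisphere = NA_character_,
                        seed = FALSE) {
  channel <- as.character(channel)
  if (anyDuplicated(channel)) stop("duplicated channel ids")
  stopifnot(length(roi) == length(channel))
  hemisphere <- rep_len(hemisphere, length(channel))
  seed <- rep_len(seed, length(channel))
  ok <- is.na(hemisphere) |
    hemisphere %in% c("ipsilesional", "contralesional", "medial")
  if (!all(ok)) stop("hemisphere must be ipsilesional, contralesional, medial or NA")
  df <- data.frame(channel = channel, roi = as.character(roi),
                   hemisphere = hemisphere, seed = as.logical(seed))
  for (r in setdiff(unique(df$roi), "unassigned")) {
    h <- unique(df$hemisphere[df$roi == r])
    if (length(h) > 1) stop("ROI ", r, " maps to more than one hemisphere")
  }
  class(df) <- c("channel_map", "data.frame")
  df
}

#' Read / write a channel map as a delimited table
#' @param path file path to a CSV with columns `channel`, `roi`,
#'   `hemisphere`, `seed`.
#' @return A [channel_map()].
#' @examples
#' map <- read_channel_map(system.file("extdata", "example_channel_map.csv",
#'                                     package = "tvgc"))
#' @export
read_channel_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  channel_map(df$channel, df$roi,
              hemisphere = df$hemisphere %||% NA_character_,
              seed = df$seed %||% FALSE)
}

#' @rdname read_channel_map
#' @param map a [channel_map()].
#' @export
write_channel_map <- function(map, path) {
  write.csv(as.data.frame(unclass(map)), path, row.names = FALSE)
  invisible(path)
}

map_channels <- function(map, roi, channels) {
  idx <- match(map$channel[map$roi == roi], channels)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("ROI ", roi, " has no channels in the GC tensor")
  idx
}

#' Pre-to-post difference of GC tensors
#'
#' Element-wise `post - pre` difference of two GC tensors sharing
#' channels and time axis: the channel-level GC change underlying all
#' region-level summaries.
#'
#' @param pre,post [conditional_gc()] results for the two phases of one
#'   hand condition.
#' @return An object of class `"delta_gc"` with the difference array
#'   (`source x target x time`).
#' @export
delta_gc <- function(pre, post) {
  stopifnot(inherits(pre, "gc_tensor"), inherits(post, "gc_tensor"))
  if (!identical(pre$channels, post$channels)) {
    stop("GC tensors have different channel sets")
  }
  if (length(pre$time) != length(post$time) ||
      max(abs(pre$time - post$time)) > 1e-6) {
    stop("GC tensors have different time axes")
  }
  structure(list(delta = post$gc - pre$gc, time = pre$time,
                 channels = pre$channels),
            class = "delta_gc")
}

#' @export
print.delta_gc <- function(x, ...) {
  cat(sprintf("Delta-GC: %d channels, %d time points in [%.2f, %.2f] s\n",
              length(x$channels), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

# pairs x time matrix of channel-level changes from ROI A to ROI B
delta_submatrix <- function(d, map, roiA, roiB) {
  if (roiA == roiB) stop("source and target ROI must differ")
  iA <- map_channels(map, roiA, d$channels)
  jB <- map_channels(map, roiB, d$channels)
  sub <- d$delta[iA, jB, , drop = FALSE]
  matrix(sub, nrow = length(iA) * length(jB), ncol = length(d$time))
}

#' Time-resolved region-level GC increase and decrease
#'
#' At each time point, the region-level increase from ROI A to ROI B is
#' the largest positive channel-level change over all pairs
#' `(i in A, j in B)`, and the decrease the smallest negative change;
#' each is set to zero when all channel-level changes are nonpositive
#' (resp. non-negative).
#'
#' @param d a [delta_gc()].
#' @param map a [channel_map()].
#' @param roiA,roiB distinct ROI labels.
#' @return Data frame with columns `time`, `increase` (>= 0) and
#'   `decrease` (<= 0).
#' @export
region_change_timeresolved <- function(d, map, roiA, roiB) {
  stopifnot(inherits(d, "delta_gc"), inherits(map, "channel_map"))
  m <- delta_submatrix(d, map, roiA, roiB)
  data.frame(time = d$time,
             increase = pmax(0, apply(m, 2, max)),
             decrease = pmin(0, apply(m, 2, min)))
}

#' Time-integrated region-level GC increase and decrease
#'
#' Per channel pair, the positive and negative channel-level changes are
#' first summed separately over the samples of the half-open window
#' `[window[1], window[2])`; the region-level increase (decrease) is then
#' the largest (smallest) of those sums over pairs, zero-clipped as in
#' [region_change_timeresolved()].
#'
#' @inheritParams region_change_timeresolved
#' @param window time window in seconds, e.g. `c(-2, 10)` for the total
#'   change or one of the half-overlapping 4 s windows `c(-2, 2)`,
#'   `c(0, 4)`, `c(2, 6)`, `c(4, 8)`, `c(6, 10)`.
#' @return Named vector `c(increase = ..., decrease = ...)`.
#' @export
region_change_integrated <- function(d, map, roiA, roiB, window) {
  stopifnot(inherits(d, "delta_gc"), inherits(map, "channel_map"))
  idx <- gc_window_indices(d$time, window)
  m <- delta_submatrix(d, map, roiA, roiB)[, idx, drop = FALSE]
  possum <- rowSums(pmax(m, 0))
  negsum <- rowSums(pmin(m, 0))
  c(increase = max(0, max(possum)), decrease = min(0, min(negsum)))
}

gc_window_indices <- function(time_s, window) {
  dt <- if (length(time_s) > 1) time_s[2] - time_s[1] else 0
  if (window[1] < time_s[1] - dt / 2 ||
      window[2] > time_s[length(time_s)] + dt + .time_tol) {
    stop(sprintf("window [%g, %g] s is outside the GC time axis [%.2f, %.2f] s",
                 window[1], window[2], time_s[1], time_s[length(time_s)]))
  }
  idx <- window_indices(time_s, window)
  if (!length(idx)) stop("window contains no samples")
  idx
}

#' Region-level summary over all ordered ROI pairs
#'
#' Applies [region_change_integrated()] to every ordered pair of
#' distinct assigned ROIs for one or more windows.
#'
#' @param d a [delta_gc()].
#' @param map a [channel_map()].
#' @param windows a named list of windows (each `c(start, end)` seconds).
#' @return A data frame of class `"region_summary"` with columns
#'   `source_roi`, `target_roi`, `window`, `increase`, `decrease`.
#' @export
region_summary <- function(d, map, windows = list(total = c(-2, 10))) {
  stopifnot(inherits(d, "delta_gc"), inherits(map, "channel_map"))
  rois <- setdiff(unique(map$roi), "unassigned")
  if (length(rois) < 2) stop("need at least two assigned ROIs")
  if (is.null(names(windows))) {
    names(windows) <- vapply(windows, function(w)
      sprintf("[%g,%g]", w[1], w[2]), character(1))
  }
  rows <- list()
  for (w in names(windows)) {
    for (a in rois) for (b in rois) {
      if (a == b) next
      v <- region_change_integrated(d, map, a, b, windows[[w]])
      rows[[length(rows) + 1L]] <- data.frame(
        source_roi = a, target_roi = b, window = w,
        increase = v[["increase"]], decrease = v[["decrease"]])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Relative change between affected- and unaffected-hand summaries
#'
#' Relative increase `dGC+_affected - dGC+_unaffected` and relative
#' decrease `|dGC-_affected| - |dGC-_unaffected|` per ordered ROI pair:
#' positive when the change is more pronounced for affected-hand use.
#'
#' @param affected,unaffected [region_summary()] results over the same
#'   ROI pairs and single window (the entire reporting window).
#' @return Data frame with `source_roi`, `target_roi`, `rel_increase`,
#'   `rel_decrease`.
#' @export
relative_change <- function(affected, unaffected) {
  stopifnot(inherits(affected, "region_summary"),
            inherits(unaffected, "region_summary"))
  key <- function(s) paste(s$source_roi, s$target_roi, s$window)
  if (!identical(sort(key(affected)), sort(key(unaffected)))) {
    stop("summaries cover different ROI pairs or windows")
  }
  u <- unaffected[match(key(affected), key(unaffected)), ]
  data.frame(source_roi = affected$source_roi,
             target_roi = affected$target_roi,
             rel_increase = affected$increase - u$increase,
             rel_decrease = abs(affected$decrease) - abs(u$decrease))
}

#' Mean connectivity change within and between hemispheres
#'
#' Averages the time-integrated region-level increases and decreases
#' over all ordered ROI pairs in three groups: within the ipsilesional
#' hemisphere (`ip-ip`), within the contralesional hemisphere (`co-co`),
#' and between hemispheres (`ip-co`, both directions pooled). Medial
#' ROIs are regarded as belonging to both hemispheres, so their pairs
#' with a lateralized ROI count in that hemisphere's within group.
#' Nonsignificant entries contribute zero to the means but stay in the
#' denominator.
#'
#' @param summary a single-window [region_summary()].
#' @param map a [channel_map()].
#' @param sig_increase,sig_decrease logical vectors aligned with the
#'   summary rows (default: all significant).
#' @return Data frame with `group`, `mean_increase`, `mean_decrease`,
#'   `n_pairs`.
#' @export
hemisphere_means <- function(summary, map, sig_increase = NULL,
                             sig_decrease = NULL) {
  stopifnot(inherits(summary, "region_summary"))
  if (length(unique(summary$window)) != 1) {
    stop("hemisphere means expect a single-window summary")
  }
  sig_increase <- sig_increase %||% rep(TRUE, nrow(summary))
  sig_decrease <- sig_decrease %||% rep(TRUE, nrow(summary))
  stopifnot(length(sig_increase) == nrow(summary),
            length(sig_decrease) == nrow(summary))
  hemi <- function(roi) {
    h <- unique(map$hemisphere[map$roi == roi])
    if (length(h) != 1 || is.na(h)) stop("ROI ", roi, " has no hemisphere tag")
    h
  }
  short <- c(ipsilesional = "ip", contralesional = "co", medial = "med")
  grp <- character(nrow(summary))
  for (r in seq_len(nrow(summary))) {
    a <- short[[hemi(summary$source_roi[r])]]
    b <- short[[hemi(summary$target_roi[r])]]
    if (a == "med") a <- b
    if (b == "med") b <- a
    grp[r] <- if (a == "med" && b == "med") NA_character_
      else if (a == b) paste0(a, "-", a)
      else "ip-co"
  }
  inc <- ifelse(sig_increase, summary$increase, 0)
  dec <- ifelse(sig_decrease, summary$decrease, 0)
  groups <- c("ip-ip", "co-co", "ip-co")
  out <- data.frame(
    group = groups,
    mean_increase = vapply(groups, function(g)
      if (any(grp == g, na.rm = TRUE)) mean(inc[grp == g & !is.na(grp)]) else 0,
      numeric(1)),
    mean_decrease = vapply(groups, function(g)
      if (any(grp == g, na.rm = TRUE)) mean(dec[grp == g & !is.na(grp)]) else 0,
      numeric(1)),
    n_pairs = vapply(groups, function(g) sum(grp == g, na.rm = TRUE),
                     integer(1)))
  rownames(out) <- NULL
  out
}

#' Total channel-level GC increases over a window
#'
#' For every ordered pair of channels assigned to any ROI (including
#' pairs within one ROI), sums the positive channel-level GC changes
#' over the window: the weighted adjacency matrix of the increases
#' graph.
#'
#' @param d a [delta_gc()].
#' @param map a [channel_map()].
#' @param window time window in seconds (default the whole `[-2, 10]` s).
#' @return A square matrix (rows = source, cols = target, diagonal `NA`)
#'   over the assigned channels.
#' @export
total_channel_increases <- function(d, map, window = c(-2, 10)) {
  stopifnot(inherits(d, "delta_gc"), inherits(map, "channel_map"))
  idx <- gc_window_indices(d$time, window)
  assigned <- map$channel[map$roi != "unassigned"]
  ci <- match(assigned, d$channels)
  if (anyNA(ci)) stop("channel map names channels absent from the tensor")
  W <- apply(pmax(d$delta[ci, ci, idx, drop = FALSE], 0), c(1, 2), sum)
  diag(W) <- NA_real_
  dimnames(W) <- list(assigned, assigned)
  W
}

#' Degree centralities of a weighted directed graph
#'
#' In-degree = sum of incoming edge weights (column sums), out-degree =
#' sum of outgoing weights (row sums), total = in + out. Rows index the
#' source node, columns the target.
#'
#' @param adjacency square numeric matrix of non-negative edge weights
#'   (diagonal may be `NA`).
#' @return Data frame with `node`, `in_degree`, `out_degree`, `total`.
#' @export
degree_centrality <- function(adjacency) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  W <- adjacency
  diag(W)[is.na(diag(W))] <- 0
  if (any(is.na(W))) stop("adjacency contains NA off the diagonal")
  if (any(W < 0)) stop("an increases graph cannot carry negative weights")
  nodes <- rownames(W) %||% as.character(seq_len(nrow(W)))
  data.frame(node = nodes, in_degree = colSums(W), out_degree = rowSums(W),
             total = colSums(W) + rowSums(W), row.names = NULL)
}

#' Seed-channel view of region-level GC increases
#'
#' Recomputes the time-integrated region-level increases with each seed
#' channel treated as a node of its own (any non-seed channels of the
#' seed ROI remain pooled as the ROI node); other ROIs stay region
#' nodes. Only increases are reported, since they primarily reflect
#' functional reorganization; zero-weight edges are dropped.
#'
#' @param d a [delta_gc()].
#' @param map a [channel_map()].
#' @param seeds seed channel ids; all must belong to one ROI.
#' @param window integration window in seconds.
#' @return Data frame with `source_node`, `target_node`, `increase`
#'   (> 0).
#' @export
seed_channel_view <- function(d, map, seeds, window = c(-2, 10)) {
  stopifnot(inherits(d, "delta_gc"), inherits(map, "channel_map"))
  seeds <- as.character(seeds)
  sroi <- unique(map$roi[map$channel %in% seeds])
  if (length(sroi) != 1 || sroi == "unassigned" ||
      !all(seeds %in% map$channel)) {
    stop("seeds must all belong to a single assigned ROI")
  }
  idx <- gc_window_indices(d$time, window)
  rois <- setdiff(unique(map$roi), "unassigned")
  nodes <- list()
  for (s in seeds) nodes[[s]] <- match(s, d$channels)
  rest <- setdiff(map$channel[map$roi == sroi], seeds)
  if (length(rest)) nodes[[sroi]] <- match(rest, d$channels)
  for (r in setdiff(rois, sroi)) nodes[[r]] <- map_channels(map, r, d$channels)

  rows <- list()
  for (a in names(nodes)) for (b in names(nodes)) {
    if (a == b) next
    sub <- d$delta[nodes[[a]], nodes[[b]], idx, drop = FALSE]
    m <- matrix(sub, nrow = length(nodes[[a]]) * length(nodes[[b]]))
    inc <- max(0, max(rowSums(pmax(m, 0))))
    if (inc > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_node = a, target_node = b, increase = inc)
    }
  }
  if (!length(rows)) {
    return(data.frame(source_node = character(), target_node = character(),
                      increase = numeric()))
  }
  do.call(rbind, rows)
}
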