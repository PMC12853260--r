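#' Analysis configuration with study-default settings
#'
#' Bundles every tunable of the full pipeline. Defaults are the settings
#' used throughout: 0.02-0.3 Hz order-4 zero-phase Butterworth band, epoch
#' \[-5, 15\] s, baseline \[-5, 0\] s, fit window \[-5, 10\] s, reporting
#' window \[-2, 10\] s, AR order 15, the five half-overlapping 4 s
#' windows, B = 1000 surrogates and FDR level q = 0.1.
#'
#' @param band bandpass edges in Hz.
#' @param filter_order bandpass filter order.
#' @param epoch_window,baseline_window,fit_window,report_window windows
#'   in seconds.
#' @param order AR order of the time-varying model.
#' @param windows named list of time-integration windows.
#' @param B surrogate count for the permutation tests.
#' @param q FDR level.
#' @param seed integer seed.
#' @param control a [tvmar_control()].
#' @param nfreq frequency-grid size for [conditional_gc()].
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(band = c(0.02, 0.3), filter_order = 4,
                            epoch_window = c(-5, 15),
                            baseline_window = c(-5, 0),
                            fit_window = c(-5, 10),
                            report_window = c(-2, 10),
                            order = 15,
                            windows = list(`w0` = c(-2, 2), `w2` = c(0, 4),
                                           `w4` = c(2, 6), `w6` = c(4, 8),
                                           `w8` = c(6, 10)),
                            B = 1000, q = 0.1, seed = 1,
                            control = tvmar_control(), nfreq = 64) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (B < 1) stop("B must be at least 1")
  stopifnot(band[1] > 0, band[1] < band[2], order >= 1,
            fit_window[1] < fit_window[2],
            report_window[1] >= fit_window[1],
            report_window[2] <= fit_window[2])
  structure(
    list(band = band, filter_order = filter_order,
         epoch_window = epoch_window, baseline_window = baseline_window,
         fit_window = fit_window, report_window = report_window,
         order = as.integer(order), windows = windows,
         B = as.integer(B), q = q, seed = as.integer(seed),
         control = control, nfreq = nfreq),
    class = "analysis_config")
}

prepare_condition <- function(input, config, map) {
  if (inherits(input, "trial_dataset")) return(input)  # already epoched
  if (inherits(input, "continuous_recording")) {
    rec <- bandpass_filter(input, config$band[1], config$band[2],
                           config$filter_order)
    if (!is.null(rec$pathway)) rec <- average_pathways(rec)
    return(epoch_and_baseline(rec, config$epoch_window,
                              config$baseline_window, channel_map = map))
  }
  stop("each input must be a trial_dataset or a continuous_recording")
}

write_table <- function(df, dir, name, manifest) {
  path <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  c(manifest, path)
}

#' Run the full connectivity-change analysis
#'
#' Orchestrates the pipeline for one pre/post pair per hand condition:
#' preprocessing (when continuous recordings are supplied), time-varying
#' model fits, conditional GC per condition, channel-level GC changes per
#' hand, region-level summaries (time-resolved, windowed, whole-window,
#' relative affected-vs-unaffected), permutation tests with BH-FDR flags,
#' hemisphere means over significant connections, the total
#' channel-level increases graph with degree centralities, and an
#' optional seed-channel view. All tables are written as delimited text,
#' arrays as RDS, plus a manifest with content digests.
#'
#' @param inputs named list with elements `pre_unaffected`,
#'   `post_unaffected`, `pre_affected`, `post_affected`; each a
#'   [trial_dataset()] (epoching is then bypassed) or a
#'   [continuous_recording()].
#' @param map a [channel_map()].
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the fits, GC tensors, summaries,
#'   permutation tables and the manifest. Deterministic given
#'   `config$seed`.
#' @export
run_full_analysis <- function(inputs, map, config = analysis_config(),
                              out_dir = tempfile("tvgc_run_")) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(map, "channel_map"))
  need <- c("pre_unaffected", "post_unaffected", "pre_affected",
            "post_affected")
  if (!all(need %in% names(inputs))) {
    stop("inputs must contain: ", paste(need, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  stage <- "preprocess"
  result <- tryCatch({
    datasets <- lapply(inputs, prepare_condition, config = config, map = map)

    stage <- "fit"
    fits <- lapply(datasets, tvmar, order = config$order,
                   window = config$fit_window, control = config$control)

    stage <- "gc"
    gcs <- lapply(fits, conditional_gc, nfreq = config$nfreq)
    for (nm in names(gcs)) {
      manifest <- write_table(as.data.frame(gcs[[nm]]), out_dir,
                              paste0("gc_", nm), manifest)
    }

    stage <- "delta"
    deltas <- list(
      unaffected = delta_gc(gcs$pre_unaffected, gcs$post_unaffected),
      affected = delta_gc(gcs$pre_affected, gcs$post_affected))

    stage <- "summarize"
    whole <- list(total = config$report_window)
    summaries <- list()
    timeres <- list()
    for (hand in names(deltas)) {
      summaries[[hand]] <- region_summary(deltas[[hand]],
                                          map, c(whole, config$windows))
      rois <- setdiff(unique(map$roi), "unassigned")
      tr <- list()
      for (a in rois) for (b in rois) {
        if (a == b) next
        df <- region_change_timeresolved(deltas[[hand]], map, a, b)
        df$source_roi <- a
        df$target_roi <- b
        tr[[paste(a, b)]] <- df
      }
      timeres[[hand]] <- do.call(rbind, tr)
      manifest <- write_table(summaries[[hand]], out_dir,
                              paste0("region_summary_", hand), manifest)
      manifest <- write_table(timeres[[hand]], out_dir,
                              paste0("region_timeresolved_", hand), manifest)
    }
    aff_total <- summaries$affected[summaries$affected$window == "total", ]
    unaff_total <- summaries$unaffected[summaries$unaffected$window == "total", ]
    class(aff_total) <- class(unaff_total) <- c("region_summary", "data.frame")
    relative <- relative_change(aff_total, unaff_total)
    manifest <- write_table(relative, out_dir, "relative_change", manifest)

    stage <- "permutation"
    rois <- setdiff(unique(map$roi), "unassigned")
    region_stat <- function(d) {
      # whole-window region-level increases/decreases, one scalar per
      # ordered ROI pair and sign
      out <- numeric(0)
      for (a in rois) for (b in rois) {
        if (a == b) next
        v <- region_change_integrated(d, map, a, b, config$report_window)
        out[paste0(a, "->", b, "+")] <- v[["increase"]]
        out[paste0(a, "->", b, "-")] <- v[["decrease"]]
      }
      out
    }
    statistic <- function(pre, post) {
      fp <- tvmar(pre, order = config$order, window = config$fit_window,
                  control = config$control)
      fq <- tvmar(post, order = config$order, window = config$fit_window,
                  control = config$control)
      region_stat(delta_gc(conditional_gc(fp, nfreq = config$nfreq),
                           conditional_gc(fq, nfreq = config$nfreq)))
    }
    perms <- list()
    for (hand in c("unaffected", "affected")) {
      pr <- permutation_test(datasets[[paste0("pre_", hand)]],
                             datasets[[paste0("post_", hand)]],
                             statistic, B = config$B,
                             seed = counter_seed(config$seed,
                                                 match(hand, c("unaffected", "affected"))))
      pr$table$fdr_significant <- bh_fdr(pr$table$p, config$q)
      perms[[hand]] <- pr
      manifest <- write_table(pr$table, out_dir,
                              paste0("permutation_", hand), manifest)
    }

    stage <- "hemisphere"
    hemi <- list()
    for (hand in c("unaffected", "affected")) {
      tot <- summaries[[hand]][summaries[[hand]]$window == "total", ]
      class(tot) <- c("region_summary", "data.frame")
      key <- paste0(tot$source_roi, "->", tot$target_roi)
      ptab <- perms[[hand]]$table
      sig_inc <- ptab$fdr_significant[match(paste0(key, "+"), ptab$id)]
      sig_dec <- ptab$fdr_significant[match(paste0(key, "-"), ptab$id)]
      hemi[[hand]] <- hemisphere_means(tot, map, sig_inc, sig_dec)
      manifest <- write_table(hemi[[hand]], out_dir,
                              paste0("hemisphere_means_", hand), manifest)
    }

    stage <- "channel_graphs"
    graphs <- list()
    for (hand in c("unaffected", "affected")) {
      W <- total_channel_increases(deltas[[hand]], map, config$report_window)
      graphs[[hand]] <- list(adjacency = W,
                             centrality = degree_centrality(W))
      manifest <- write_table(as.data.frame(W), out_dir,
                              paste0("channel_increases_", hand), manifest)
      manifest <- write_table(graphs[[hand]]$centrality, out_dir,
                              paste0("degree_centrality_", hand), manifest)
    }
    seeds <- map$channel[map$seed]
    seed_views <- NULL
    if (length(seeds)) {
      seed_views <- lapply(deltas, seed_channel_view, map = map,
                           seeds = seeds, window = config$report_window)
      for (hand in names(seed_views)) {
        manifest <- write_table(seed_views[[hand]], out_dir,
                                paste0("seed_view_", hand), manifest)
      }
    }

    stage <- "serialize"
    rds_path <- file.path(out_dir, "arrays.rds")
    saveRDS(list(fits = fits, gcs = gcs, deltas = deltas), rds_path)
    manifest <- c(manifest, rds_path)

    digests <- tools::md5sum(manifest)
    mdf <- data.frame(file = basename(manifest), md5 = unname(digests))
    write.csv(mdf, file.path(out_dir, "manifest.csv"), row.names = FALSE)

    list(datasets = datasets, fits = fits, gc = gcs, deltas = deltas,
         summaries = summaries, timeresolved = timeres,
         relative = relative, permutations = perms,
         hemisphere_means = hemi, channel_graphs = graphs,
         seed_views = seed_views, manifest = mdf, out_dir = out_dir)
  }, error = function(e) {
    writeLines(c(paste0("stage: ", stage), conditionMessage(e)),
               failed_marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
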