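make_gc <- function(arr, time = NULL, channels = NULL) {
  channels <- channels %||% paste0("ch", seq_len(dim(arr)[1]))
  time <- time %||% (seq_len(dim(arr)[3]) - 1) * 0.13
  dimnames(arr) <- list(channels, channels, NULL)
  structure(list(gc = arr, raw = arr, time = time, channels = channels,
                 method = "efficient",
                 diagnostics = list(clipped_fraction = 0, nonconverged = 0)),
            class = "gc_tensor")
}

test_that("delta_gc is the element-wise post minus pre difference", {
  a <- array(abs(rnorm(3 * 3 * 4)), c(3, 3, 4))
  b <- a
  b[1, 2, ] <- b[1, 2, ] + 0.1
  ga <- make_gc(a); gb <- make_gc(b)
  expect_true(all(delta_gc(ga, ga)$delta == 0))
  d <- delta_gc(ga, gb)
  expect_equal(d$delta[1, 2, ], rep(0.1, 4))
  expect_equal(sum(abs(d$delta)), 0.4)
  # anti-symmetry
  expect_equal(delta_gc(ga, gb)$delta, -delta_gc(gb, ga)$delta)
  # axis mismatch rejected
  gshort <- make_gc(a[, , 1:3])
  expect_error(delta_gc(ga, gshort), "time axes")
  g2 <- make_gc(a, channels = c("x", "y", "z"))
  expect_error(delta_gc(ga, g2), "channel sets")
})

test_that("time-resolved region changes take the extreme channel changes", {
  map <- toy_map3()
  # pairs (1,3) and (2,3); single time point with diffs +0.3 / -0.1
  d <- fake_delta(array(0, c(3, 3, 1)))
  d$delta[1, 3, 1] <- 0.3
  d$delta[2, 3, 1] <- -0.1
  out <- region_change_timeresolved(d, map, "A", "B")
  expect_equal(out$increase, 0.3)
  expect_equal(out$decrease, -0.1)

  # all diffs negative -> increase clipped to zero
  d2 <- fake_delta(array(0, c(3, 3, 1)))
  d2$delta[1, 3, 1] <- -0.2
  d2$delta[2, 3, 1] <- -0.05
  out2 <- region_change_timeresolved(d2, map, "A", "B")
  expect_equal(out2$increase, 0)
  expect_equal(out2$decrease, -0.2)

  # single-channel ROIs
  d3 <- fake_delta(array(0, c(3, 3, 1)))
  d3$delta[3, 1, 1] <- 0.07
  out3 <- region_change_timeresolved(d3, map, "B", "A")
  expect_equal(out3$increase, 0.07)
  expect_equal(out3$decrease, 0)

  expect_error(region_change_timeresolved(d, map, "A", "A"), "differ")
  expect_error(region_change_timeresolved(d, map, "A", "Z"), "no channels")
})

test_that("time-integrated region changes sum signed parts before extremes", {
  map <- toy_map3()
  d <- fake_delta(array(0, c(3, 3, 3)), time = c(0, 0.13, 0.26))
  d$delta[1, 3, ] <- c(0.2, -0.1, 0.3)  # positive sum 0.5, negative sum -0.1
  out <- region_change_integrated(d, map, "A", "B", c(0, 0.39))
  expect_equal(out[["increase"]], 0.5)
  expect_equal(out[["decrease"]], -0.1)

  zero <- fake_delta(array(0, c(3, 3, 3)))
  expect_equal(unname(region_change_integrated(zero, map, "A", "B", c(0, 0.39))),
               c(0, 0))
  expect_error(region_change_integrated(d, map, "A", "B", c(5, 6)),
               "outside")
})

test_that("the five 4 s windows are half-overlapping and tile [-2, 10)", {
  time <- seq(-2, 10 - 0.13, by = 0.13)
  wins <- list(c(-2, 2), c(0, 4), c(2, 6), c(4, 8), c(6, 10))
  idx <- lapply(wins, function(w) tvgc:::window_indices(time, w))
  for (k in 1:4) {
    overlap <- intersect(idx[[k]], idx[[k + 1]])
    half <- tvgc:::window_indices(time, c(wins[[k + 1]][1], wins[[k]][2]))
    expect_identical(overlap, half)
    # the overlap spans exactly half of each window's samples, up to grid
    expect_lt(abs(length(overlap) - length(idx[[k]]) / 2), 2)
  }
  expect_identical(sort(unique(unlist(idx))), seq_along(time))
})

test_that("whole-window integration equals integration over the tiled union", {
  map <- toy_map3()
  set.seed(31)
  for (rep in 1:5) {
    time <- seq(-2, 10, by = 0.13)
    time <- time[time < 10]
    d <- fake_delta(array(rnorm(3 * 3 * length(time)), c(3, 3, length(time))),
                    time = time)
    whole <- region_change_integrated(d, map, "A", "B", c(-2, 10))
    union_idx <- sort(unique(unlist(lapply(
      list(c(-2, 2), c(0, 4), c(2, 6), c(4, 8), c(6, 10)),
      function(w) tvgc:::window_indices(time, w)))))
    m <- d$delta[1:2, 3, union_idx]
    manual <- c(increase = max(0, max(rowSums(pmax(m, 0)))),
                decrease = min(0, min(rowSums(pmin(m, 0)))))
    expect_equal(whole, manual)
  }
})

test_that("enlarging a ROI can only widen the region-level extremes", {
  set.seed(32)
  for (rep in 1:5) {
    d <- fake_delta(array(rnorm(4 * 4 * 6), c(4, 4, 6)))
    map_small <- channel_map(paste0("ch", 1:4), c("A", "X", "B", "B"),
                             hemisphere = "ipsilesional")
    map_big <- channel_map(paste0("ch", 1:4), c("A", "A", "B", "B"),
                           hemisphere = "ipsilesional")
    w <- c(0, 6 * 0.13)
    small <- region_change_integrated(d, map_small, "A", "B", w)
    big <- region_change_integrated(d, map_big, "A", "B", w)
    expect_gte(big[["increase"]], small[["increase"]])
    expect_lte(big[["decrease"]], small[["decrease"]])
  }
})

test_that("relative changes follow the affected-minus-unaffected convention", {
  map <- toy_map3()
  mk <- function(inc, dec) {
    out <- data.frame(source_roi = "A", target_roi = "B", window = "total",
                      increase = inc, decrease = dec)
    class(out) <- c("region_summary", "data.frame")
    out
  }
  r1 <- relative_change(mk(0.4, 0), mk(0.1, 0))
  expect_equal(r1$rel_increase, 0.3)
  r2 <- relative_change(mk(0, -0.2), mk(0, -0.5))
  expect_equal(r2$rel_decrease, -0.3)
  r3 <- relative_change(mk(0.2, -0.1), mk(0.2, -0.1))
  expect_equal(r3$rel_increase, 0)
  expect_equal(r3$rel_decrease, 0)
  bad <- mk(1, 0); bad$target_roi <- "C"
  expect_error(relative_change(mk(1, 0), bad), "different ROI pairs")
})

test_that("hemisphere means pool significant pairs with medial in both", {
  map <- channel_map(paste0("ch", 1:7),
                     roi = c("A", "A", "B", "C", "C", "S", "U"),
                     hemisphere = c("ipsilesional", "ipsilesional",
                                    "ipsilesional", "contralesional",
                                    "contralesional", "medial", NA))
  map$roi[7] <- "unassigned"
  rois <- c("A", "B", "C", "S")
  grid <- expand.grid(source_roi = rois, target_roi = rois,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source_roi != grid$target_roi, ]
  s <- data.frame(grid, window = "total", increase = 0.3, decrease = -0.2)
  class(s) <- c("region_summary", "data.frame")

  # all significant and equal: every group mean equals the common value
  hm <- hemisphere_means(s, map)
  expect_equal(hm$mean_increase, rep(0.3, 3))
  expect_equal(hm$mean_decrease, rep(-0.2, 3))
  # medial ROI pairs count within both hemispheres: ip-ip holds A<->B,
  # A<->S, B<->S (6 ordered); co-co holds C<->S (2); ip-co the rest (4)
  expect_equal(hm$n_pairs[hm$group == "ip-ip"], 6L)
  expect_equal(hm$n_pairs[hm$group == "co-co"], 2L)
  expect_equal(hm$n_pairs[hm$group == "ip-co"], 4L)

  # nothing significant: all means zero
  hm0 <- hemisphere_means(s, map, sig_increase = rep(FALSE, nrow(s)),
                          sig_decrease = rep(FALSE, nrow(s)))
  expect_equal(hm0$mean_increase, rep(0, 3))
  expect_equal(hm0$mean_decrease, rep(0, 3))

  # nonsignificant entries contribute zero but stay in the denominator
  s2 <- s[s$source_roi == "A" & s$target_roi == "B" |
          s$source_roi == "B" & s$target_roi == "A", ]
  class(s2) <- c("region_summary", "data.frame")
  s2$increase <- c(0.4, 0.2)
  hm2 <- hemisphere_means(s2, map, sig_increase = c(TRUE, FALSE))
  expect_equal(hm2$mean_increase[hm2$group == "ip-ip"], 0.2)
})

test_that("degree centralities are signed edge-weight sums", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 1; W["b", "c"] <- 2; W["a", "c"] <- 3
  dc <- degree_centrality(W)
  expect_equal(dc$out_degree[dc$node == "a"], 4)
  expect_equal(dc$in_degree[dc$node == "c"], 5)
  expect_equal(dc$total[dc$node == "a"], 4)

  W1 <- matrix(0, 2, 2); W1[1, 2] <- 5
  dc1 <- degree_centrality(W1)
  expect_equal(dc1$out_degree, c(5, 0))
  expect_equal(dc1$in_degree, c(0, 5))

  W2 <- matrix(0, 2, 2); W2[1, 2] <- W2[2, 1] <- 2
  expect_equal(degree_centrality(W2)$total, c(4, 4))

  Wneg <- W; Wneg["a", "b"] <- -1
  expect_error(degree_centrality(Wneg), "negative")
})

test_that("total channel increases include within-ROI pairs", {
  map <- toy_map3()
  time <- c(0, 0.13)
  d <- fake_delta(array(0, c(3, 3, 2)), time = time)
  d$delta[1, 2, ] <- c(0.2, -0.1)  # within ROI A
  d$delta[1, 3, ] <- c(0.3, 0.1)
  W <- total_channel_increases(d, map, window = c(0, 0.26))
  expect_equal(W["ch1", "ch2"], 0.2)
  expect_equal(W["ch1", "ch3"], 0.4)
  expect_true(is.na(W["ch1", "ch1"]))
})

test_that("seed-channel views split the seed ROI per channel", {
  # one seed, no other channel in its ROI: identical to the region result
  map <- toy_map3()  # B = {ch3}
  time <- (0:2) * 0.13
  d <- fake_delta(array(0, c(3, 3, 3)), time = time)
  d$delta[3, 1, ] <- c(0.2, 0.1, -0.1)
  sv <- seed_channel_view(d, map, seeds = "ch3", window = c(0, 0.39))
  reg <- region_change_integrated(d, map, "B", "A", c(0, 0.39))
  expect_equal(sv$increase[sv$source_node == "ch3" & sv$target_node == "A"],
               reg[["increase"]])

  # two seeds with distinct inflows stay separate
  map2 <- channel_map(paste0("ch", 1:4), roi = c("P", "P", "Q", "Q"),
                      hemisphere = "ipsilesional")
  d2 <- fake_delta(array(0, c(4, 4, 2)), time = c(0, 0.13))
  d2$delta[3, 1, 1] <- 0.5  # ch3 -> seed ch1
  d2$delta[3, 2, 1] <- 0.2  # ch3 -> seed ch2
  sv2 <- seed_channel_view(d2, map2, seeds = c("ch1", "ch2"),
                           window = c(0, 0.26))
  expect_equal(sv2$increase[sv2$target_node == "ch1"], 0.5)
  expect_equal(sv2$increase[sv2$target_node == "ch2"], 0.2)

  # all-negative changes: empty increases graph
  d3 <- fake_delta(array(-0.1, c(4, 4, 2)), time = c(0, 0.13))
  expect_equal(nrow(seed_channel_view(d3, map2, seeds = "ch1",
                                      window = c(0, 0.26))), 0)

  expect_error(seed_channel_view(d2, map2, seeds = c("ch1", "ch3"),
                                 window = c(0, 0.26)), "single assigned ROI")
})
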