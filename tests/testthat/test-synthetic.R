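test_that("uncoupled unit-noise network yields unit-variance white channels", {
  net <- var_network(2, self = 0)
  cfg <- scenario_config(n_trials = 200, n_time = 100, onset_index = 39,
                         seed = 101)
  d <- generate_trials(net, cfg)
  v <- apply(d$x, 1, function(m) var(as.vector(m)))
  expect_true(all(abs(v - 1) < 0.05))
})

test_that("generation is byte-identical under a fixed seed", {
  net <- bivariate_net()
  cfg <- scenario_config(n_trials = 20, n_time = 60, onset_index = 10,
                         seed = 7, measurement_noise_sd = 0.1,
                         amplitude_sd = 0.2)
  expect_identical(generate_trials(net, cfg)$x, generate_trials(net, cfg)$x)
})

test_that("lag-1 cross-covariance matches the Yule-Walker relation", {
  # x2(t) = 0.5 x1(t-1) + e2 => cov(x1(t-1), x2(t)) = 0.5 var(x1)
  net <- bivariate_net(0.5)
  cfg <- scenario_config(n_trials = 1000, n_time = 101, onset_index = 10,
                         seed = 11)
  d <- generate_trials(net, cfg)
  x1_lag <- as.vector(d$x[1, 1:100, ])
  x2_now <- as.vector(d$x[2, 2:101, ])
  expect_gte(length(x1_lag), 1e5)
  expect_lt(abs(cov(x1_lag, x2_now) - 0.5 * var(as.vector(d$x[1, , ]))), 0.02)
})

test_that("unstable schedules and invalid noise covariances are rejected", {
  coeffs <- array(0, dim = c(2, 2, 1, 5))
  coeffs[1, 1, 1, ] <- 0.5
  coeffs[1, 1, 1, 3] <- 1.2  # unstable only at time index 3
  expect_error(ground_truth_network(coeffs), "time index 3")
  expect_error(ground_truth_network(array(0.3 * diag(2), c(2, 2, 1)),
                                    noise_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(ground_truth_network(array(c(0.3, NA, 0, 0.3), c(2, 2, 1))),
               "finite")
})

test_that("condition pairs report exactly the planted coupling changes", {
  cfg <- scenario_config(n_trials = 5, n_time = 30, onset_index = 10, seed = 2)
  base <- var_network(3, self = 0.3)

  same <- make_condition_pair(base, base, cfg)
  expect_equal(nrow(same$change_map), 0)

  up <- var_network(3, self = 0.3,
                    couplings = data.frame(source = 1, target = 2, value = 0.5))
  one <- make_condition_pair(base, up, cfg)
  expect_equal(nrow(one$change_map), 1)
  expect_equal(one$change_map$source, 1)
  expect_equal(one$change_map$target, 2)
  expect_equal(one$change_map$direction, "increase")

  pre2 <- var_network(3, self = 0.3,
                      couplings = data.frame(source = 2, target = 3, value = 0.4))
  post2 <- var_network(3, self = 0.3,
                       couplings = data.frame(source = c(2, 1), target = c(3, 2),
                                              value = c(0.1, 0.5)))
  both <- make_condition_pair(pre2, post2, cfg)
  expect_setequal(both$change_map$direction, c("increase", "decrease"))
  expect_equal(sum(both$change_map$direction == "increase"), 1)
  expect_equal(sum(both$change_map$direction == "decrease"), 1)

  expect_error(make_condition_pair(base, bivariate_net(), cfg),
               "channel counts differ")
})

test_that("analytic GC oracle is exact on closed-form cases", {
  # no cross-coupling -> zero for every ordered pair
  net_d <- var_network(3, self = c(0.4, 0.2, 0.5))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_lt(abs(analytic_gc_stationary(net_d, i, j)), 1e-10)
  }
  # x1 white, x2 = 0.5 x1(t-1) + e2: GC(1->2) = ln(1.25), GC(2->1) = 0
  net <- bivariate_net(0.5)
  expect_equal(analytic_gc_stationary(net, 1, 2), log(1.25), tolerance = 1e-8)
  expect_lt(abs(analytic_gc_stationary(net, 2, 1)), 1e-10)
  # time-varying schedules are outside the oracle's domain
  tv <- var_network(2, self = 0.3, n_time = 4,
                    couplings = data.frame(source = 1, target = 2, value = 0.5,
                                           from = 3, to = 4))
  expect_error(analytic_gc_stationary(tv, 1, 2), "time-invariant")
})

test_that("analytic oracle agrees with simulation plus least-squares fits", {
  # independent route: long simulation, then OLS full and reduced AR fits
  sim_ls_gc <- function(net, source, target, lags, n = 2e5, seed = 31) {
    cfg <- scenario_config(n_trials = 1, n_time = n, onset_index = 1,
                           seed = seed)
    x <- t(generate_trials(net, cfg)$x[, , 1])
    fit_resid_var <- function(cols) {
      E <- embed(x[, cols, drop = FALSE], lags + 1)
      y <- E[, match(target, cols)]
      Z <- E[, -(seq_along(cols)), drop = FALSE]
      r <- lm.fit(cbind(1, Z), y)$residuals
      sum(r^2) / length(r)
    }
    full <- fit_resid_var(seq_len(net$n_channels))
    red <- fit_resid_var(setdiff(seq_len(net$n_channels), source))
    log(red / full)
  }
  net2 <- bivariate_net(0.5)
  gc_sim <- sim_ls_gc(net2, 1, 2, lags = 10)
  expect_lt(abs(gc_sim / analytic_gc_stationary(net2, 1, 2) - 1), 0.02)

  net3 <- var_network(3, self = c(0.4, 0.3, 0.2),
                      couplings = data.frame(source = c(1, 2), target = c(2, 3),
                                             value = c(0.5, 0.4)))
  gc_sim3 <- sim_ls_gc(net3, 1, 2, lags = 15)
  expect_lt(abs(gc_sim3 / analytic_gc_stationary(net3, 1, 2) - 1), 0.02)
})

test_that("trial datasets round-trip through the delimited text format", {
  net <- bivariate_net()
  cfg <- scenario_config(n_trials = 3, n_time = 20, onset_index = 5, seed = 9)
  d <- generate_trials(net, cfg, condition = "pre")
  path <- tempfile(fileext = ".csv")
  write_trials(d, path)
  d2 <- read_trials(path)
  expect_equal(d2$x, d$x)
  expect_equal(d2$dt, d$dt)
  expect_equal(d2$onset_index, d$onset_index)
  expect_equal(d2$condition, "pre")
})
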