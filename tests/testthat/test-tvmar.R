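test_that("coefficients of a time-invariant VAR are recovered across trials", {
  net <- var_network(3, self = c(0.4, 0.3, 0.2),
                     couplings = data.frame(source = c(1, 2), target = c(2, 3),
                                            value = c(0.5, -0.4)))
  cfg <- scenario_config(n_trials = 200, n_time = 100, onset_index = 39,
                         seed = 11)
  fit <- tvmar(generate_trials(net, cfg), order = 1)
  post_burn <- which(fit$time >= fit$time[1] + 3)
  Atrue <- net$coeffs[, , 1, 1]
  err <- vapply(post_burn, function(s)
    mean(abs(fit$coefficients[, , 1, s] - Atrue)), numeric(1))
  expect_lt(mean(err), 0.1)

  # graceful degradation at fewer trials
  cfg_small <- scenario_config(n_trials = 40, n_time = 100, onset_index = 39,
                               seed = 12)
  fit_small <- tvmar(generate_trials(net, cfg_small), order = 1)
  err_small <- vapply(post_burn, function(s)
    mean(abs(fit_small$coefficients[, , 1, s] - Atrue)), numeric(1))
  expect_lt(mean(err_small), 0.2)
})

test_that("all-zero data leaves coefficients at their zero initialization", {
  d <- trial_dataset(array(0, c(2, 40, 5)), dt = 0.13, onset_index = 10)
  fit <- tvmar(d, order = 2)
  expect_true(all(fit$coefficients == 0))
})

test_that("a mid-epoch step in coupling is tracked within 2 s", {
  net <- var_network(2, self = 0.3, n_time = 120,
                     couplings = data.frame(source = 1, target = 2, value = 0.5,
                                            from = 61, to = 120))
  cfg <- scenario_config(n_trials = 200, n_time = 120, onset_index = 39,
                         seed = 12)
  d <- generate_trials(net, cfg)
  fit <- tvmar(d, order = 1)
  step_time <- trial_time(d)[61]
  traj <- fit$coefficients[2, 1, 1, ]
  crossed <- fit$time[fit$time >= step_time & traj >= 0.25]
  expect_gt(length(crossed), 0)
  expect_lt(min(crossed) - step_time, 2)
})

test_that("residual variances reflect the generating innovation scale", {
  # white noise: model explains nothing, residual variance ~ 1
  cfg <- scenario_config(n_trials = 150, n_time = 80, onset_index = 20,
                         seed = 13)
  fw <- tvmar(generate_trials(var_network(2, self = 0), cfg), order = 1)
  t_late <- length(fw$time)
  for (ch in 1:2) {
    expect_lt(abs(residual_variance(fw, ch, t_late) - 1), 0.15)
  }

  # near-deterministic target: residual variance near the jitter variance
  netp <- ground_truth_network(array(diag(c(0.3, 0.9)), c(2, 2, 1)),
                               noise_cov = diag(c(1, 1e-4)))
  fp <- tvmar(generate_trials(netp, cfg), order = 1)
  expect_lt(residual_variance(fp, 2, t_late), 5e-4)
  expect_gt(residual_variance(fp, 2, t_late), 2e-5)

  # bivariate analytic scenario: full-model residual variance of ch2 ~ 1
  fb <- tvmar(generate_trials(bivariate_net(0.5), cfg), order = 1)
  expect_lt(abs(residual_variance(fb, 2, t_late) - 1), 0.15)

  expect_error(residual_variance(fb, 2, 10000), "outside the fitted window")
})

test_that("time-averaged coefficients approach the pooled OLS estimate", {
  net <- four_channel_net()
  cfg <- scenario_config(n_trials = 150, n_time = 90, onset_index = 20,
                         seed = 14)
  d <- generate_trials(net, cfg)
  fit <- tvmar(d, order = 1)
  post_burn <- fit$time >= fit$time[1] + 3
  A_kalman <- apply(fit$coefficients[, , 1, post_burn], c(1, 2), mean)

  # pooled least squares over all trials and (post-burn-in) times
  Y <- NULL; Z <- NULL
  tt_idx <- which(trial_time(d) >= fit$time[1] + 3)
  for (r in seq_len(dim(d$x)[3])) {
    Y <- rbind(Y, t(d$x[, tt_idx, r]))
    Z <- rbind(Z, t(d$x[, tt_idx - 1, r]))
  }
  A_ols <- t(qr.solve(Z, Y))
  expect_lt(mean(abs(A_kalman - A_ols)), 0.05)
})

test_that("fitting is invariant to trial ordering", {
  net <- bivariate_net(0.5)
  cfg <- scenario_config(n_trials = 30, n_time = 50, onset_index = 10,
                         seed = 15)
  d <- generate_trials(net, cfg)
  perm <- rev(seq_len(30))
  d2 <- trial_dataset(d$x[, , perm], dt = d$dt, onset_index = d$onset_index)
  f1 <- tvmar(d, order = 1)
  f2 <- tvmar(d2, order = 1)
  expect_lt(max(abs(f1$coefficients - f2$coefficients)), 1e-10)
  expect_lt(max(abs(f1$sigma - f2$sigma)), 1e-10)
})

test_that("innovation covariances stay symmetric positive semidefinite", {
  net <- four_channel_net()
  cfg <- scenario_config(n_trials = 50, n_time = 60, onset_index = 10,
                         seed = 16)
  fit <- tvmar(generate_trials(net, cfg), order = 2)
  for (s in seq_along(fit$time)) {
    S <- fit$sigma[, , s]
    expect_true(isSymmetric(S, tol = 1e-10))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("degenerate fit requests are rejected", {
  d <- trial_dataset(array(rnorm(2 * 20 * 5), c(2, 20, 5)), dt = 0.13,
                     onset_index = 5)
  expect_error(tvmar(d, order = 25), "more than p")
  one_trial <- trial_dataset(array(rnorm(2 * 20), c(2, 20, 1)), dt = 0.13,
                             onset_index = 5)
  expect_error(tvmar(one_trial, order = 2), "2 trials")
})

test_that("fit methods expose coefficients, variances and predictions", {
  net <- bivariate_net(0.5)
  cfg <- scenario_config(n_trials = 40, n_time = 60, onset_index = 10,
                         seed = 17)
  d <- generate_trials(net, cfg)
  fit <- tvmar(d, order = 1)
  expect_equal(dim(coef(fit)), c(2, 2, 1, length(fit$time)))
  expect_equal(dim(sigma(fit)), c(length(fit$time), 2))
  expect_true(all(sigma(fit) > 0))
  pred <- predict(fit)
  expect_equal(dim(pred), c(2, length(fit$time), 40))
  res <- residuals(fit)
  # one-step residual variance of the driven channel near the innovation scale
  expect_lt(abs(var(as.vector(res[2, -(1:25), ])) - 1), 0.2)
  sim <- simulate(fit, nsim = 5, seed = 1)
  expect_s3_class(sim, "trial_dataset")
  expect_equal(dim(sim$x), c(2, length(fit$time), 5))
  expect_output(print(fit), "Time-varying VAR")
  expect_output(print(summary(fit)), "adaptation")
})
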