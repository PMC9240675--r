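test_that("front-speed estimator recovers synthetic interface tracks", {
  # exact linear track: slope recovered exactly, R^2 = 1
  t <- seq(0, 20, by = 0.05)
  traj <- list(t = t, s_hat = 2.5e-6 - 0.05e-6 * t, scales = NULL)
  fs <- estimate_front_speed(traj)
  expect_equal(fs$v_hat, -5e-8, tolerance = 1e-12)
  expect_gte(fs$r_squared, 1 - 1e-12)
  # exponential transient into a linear tail of slope -30 nm/s
  s2 <- 2.5e-6 - 0.03e-6 * t + 0.3e-6 * exp(-t / 1.5)
  fs2 <- estimate_front_speed(list(t = t, s_hat = s2))
  expect_rel_equal(fs2$v_hat, -3e-8, 0.01)
  # window excludes the transient
  expect_gt(fs2$window[1], 1.5)
  # noise with no drift: no travelling regime
  set.seed(7)
  s3 <- 2.5e-6 + cumsum(stats::rnorm(length(t), 0, 1e-9))
  expect_error(estimate_front_speed(list(t = t, s_hat = s3)),
               "no travelling regime")
})

test_that("power-law fitter is exact on noiseless data and calibrated under noise", {
  A <- 3; a <- -2.2; Fc <- 0.5
  forces <- Fc + 10^seq(-2, 0, length.out = 12)   # two decades in F - Fc
  tf <- A * (forces - Fc)^a
  fit <- fit_power_law(forces, tf)
  expect_rel_equal(fit$a, a, 1e-6)
  expect_rel_equal(fit$F_c, Fc, 1e-6)
  expect_rel_equal(fit$A, A, 1e-5)
  # zero-noise bias on a different (coarser, shifted) grid
  forces8 <- Fc + 10^seq(-1.5, 0.5, length.out = 8)
  fit8 <- fit_power_law(forces8, A * (forces8 - Fc)^a)
  expect_lt(abs(fit8$a - a), 0.05)
  # Monte-Carlo calibration: 5% multiplicative lognormal noise, 12 forces;
  # the exponent lands within +/- 0.2 in at least 95% of seeded replicates
  set.seed(2024)
  n_rep <- 200
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tf_n <- tf * exp(stats::rnorm(length(tf), 0, 0.05))
    f_r <- tryCatch(fit_power_law(forces, tf_n, seed = r),
                    error = function(e) NULL)
    ok[r] <- !is.null(f_r) && abs(f_r$a - a) <= 0.2
  }
  expect_gte(mean(ok), 0.95)
  # too few finite points is an error
  expect_error(fit_power_law(forces[1:4], tf[1:4]), ">= 5")
})

test_that("failure-time sweeps are monotone in force and cached", {
  sw <- mixed_sweep()
  finite <- is.finite(sw$t_fail)
  expect_gte(sum(finite), 5)
  # stronger driving cannot slow failure
  expect_true(all(diff(sw$t_fail[order(sw$F_over_gamma)]) <= 0))
  # caching: a re-run of an identical (cheap) sweep performs no simulations
  cache <- file.path(tempdir(), "mempeel_cache_test")
  unlink(cache, recursive = TRUE)
  p <- regime_params("mixed")
  t_first <- system.time(
    s1 <- sweep_failure_times(p, c(0.6, 0.68), t_end = 15, resolution = 4,
                              step_tol = 0.06, cache_dir = cache))["elapsed"]
  t_second <- system.time(
    s2 <- sweep_failure_times(p, c(0.6, 0.68), t_end = 15, resolution = 4,
                              step_tol = 0.06, cache_dir = cache))["elapsed"]
  expect_equal(s1$t_fail, s2$t_fail)
  expect_equal(s1$status, s2$status)
  expect_gte(length(list.files(cache)), 2)
  expect_lt(t_second, t_first / 2)
  unlink(cache, recursive = TRUE)
})

test_that("mixed-regime lifetimes follow a sharp power law in F - F_c", {
  sw <- mixed_sweep()
  fit <- fit_power_law(sw$F_over_gamma, sw$t_fail)
  # a clean power law: tiny log-space residual over a 40-fold lifetime range
  expect_lt(fit$residual, 0.05)
  expect_gt(max(fit$t_fail) / min(fit$t_fail), 20)
  # an abrupt strength threshold: steeply diverging lifetime, F_c below
  # every simulated force but well above zero
  expect_lt(fit$a, -1.5)
  expect_true(all(fit$forces > fit$F_c))
  expect_gt(fit$F_c, 0.1)
})

test_that("crowding weakens the patch: failure accelerates as cmax drops", {
  # inside the model's failing force window the crowded patch (cmax = 5 c0)
  # fails while the nearly-dilute one (cmax = 500 c0) arrests ...
  tr5_36 <- crowding_run(5, 2000, F_over_gamma = 0.36)
  tr500_36 <- crowding_run(500, 2000, F_over_gamma = 0.36)
  expect_true(is.finite(tr5_36$t_fail))
  expect_lt(tr5_36$t_fail, tr500_36$t_fail)   # Inf counts as later
  # ... and at a force where both fail, crowding fails much faster
  tr5_42 <- crowding_run(5, 2000, F_over_gamma = 0.42)
  tr500_42 <- crowding_run(500, 2000, F_over_gamma = 0.42)
  expect_true(is.finite(tr5_42$t_fail) && is.finite(tr500_42$t_fail))
  expect_lt(tr5_42$t_fail, tr500_42$t_fail)
  # intermediate crowding is intermediate in shrinkage at matched times
  tr20_36 <- crowding_run(20, 2000, F_over_gamma = 0.36)
  t_cmp <- 0.99 * min(max(tr5_36$t), max(tr20_36$t), max(tr500_36$t))
  s_at <- function(tr) stats::approx(tr$t, tr$s_hat, xout = t_cmp)$y
  expect_lt(s_at(tr5_36), s_at(tr20_36))
  expect_lte(s_at(tr20_36), s_at(tr500_36))
})

test_that("below-threshold forces do not fail within the observation window", {
  fx <- fixture("mixed_low_force", function() {
    run_peeling(regime_params("mixed", F_over_gamma = 0.15), t_end = 250,
                resolution = 3, step_tol = 0.04)
  })
  expect_false(is.finite(fx$t_fail))
  # the patch settles toward a stable configuration: late drift is tiny
  n <- length(fx$t)
  idx <- fx$t > 0.8 * fx$t[n]
  drift <- (max(fx$s_hat[idx]) - min(fx$s_hat[idx])) / fx$s_hat[n]
  expect_lt(drift, 0.02)
  # chemical potentials are far along toward mu1 = 2 mu2 equilibration
  # (full uniformization continues on the slow vesicle-scale time tau_diff2)
  arr <- is_arrested(fx, window = 0.2, tol_s = 0.02, tol_mu = 0.2)
  expect_lt(arr$mu_gap, 0.2)
})
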