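# Shared fixtures. Heavy simulation runs are memoised so that solver,
# experiment and acceptance tests reuse the same trajectories.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# constant-theta diffusion-regime (Stefan) run at driving parameter U,
# integrated to tau = 0.05 with profile snapshots; the default resolution
# is finer than the solver default because the similarity comparison is a
# convergence statement (steeper layers at larger U need more cells)
stefan_run <- function(U, resolution = 0.5) {
  fixture(sprintf("stefan_U%g_r%g", U, resolution), function() {
    p <- regime_params("diffusion", constant_theta = TRUE)
    eq <- prepare_equilibrium(p)
    scl <- derive_scales(p, c1ref = eq$c1_eq, gamma = eq$gamma_eq)
    theta_U <- acos(1 - U * (1 - cos(eq$theta0)))
    tr <- run_peeling(p, t_end = 0.05 * scl$tau_diff1, theta_fixed = theta_U,
                      resolution = resolution, step_tol = 0.01,
                      snap_times = c(0.01, 0.025, 0.05) * scl$tau_diff1)
    list(traj = tr, U = U, theta = theta_U, params = p, eq = eq, scl = scl)
  })
}

# reaction-dominated travelling-front run at contact angle theta_deg
front_run <- function(theta_deg, f_beta_over_f_gamma = 4, t_end = 5,
                      resolution = 2) {
  key <- sprintf("front_th%g_fb%g_t%g_r%g", theta_deg, f_beta_over_f_gamma,
                 t_end, resolution)
  fixture(key, function() {
    f_gamma <- sqrt(2.5e-4 * 4.11e-21)
    p <- regime_params("reaction",
                       f_beta = f_beta_over_f_gamma * f_gamma)
    run_peeling(p, t_end = t_end, theta_fixed = theta_deg * pi / 180,
                resolution = resolution)
  })
}

# mixed-regime failure-time sweep (coarse preset)
mixed_sweep <- function() {
  fixture("mixed_sweep", function() {
    p <- regime_params("mixed")
    # geometric ladder in F - Fc_est above the estimated arrest threshold
    # Fc_est ~ 0.39 (arrest at 0.38, failure at 0.40 in this preset)
    forces <- c(0.40, 0.4097, 0.429, 0.467, 0.5419, 0.69)
    sweep_failure_times(p, forces, t_end = 6000, resolution = 2,
                        step_tol = 0.04)
  })
}

crowding_run <- function(cmax_over_c0, t_end, F_over_gamma = 0.3) {
  fixture(sprintf("crowd_%g_%g_%g", cmax_over_c0, t_end, F_over_gamma),
          function() {
    p <- regime_params("crowding", F_over_gamma = F_over_gamma,
                       cmax = cmax_over_c0 * 2.5e15)
    run_peeling(p, t_end = t_end, resolution = 2, step_tol = 0.04)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
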