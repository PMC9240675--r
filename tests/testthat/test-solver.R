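test_that("interface velocity: zero-flux and manufactured-gradient cases", {
  p <- peel_params()
  s_hat <- p$s_hat0
  s <- seq(0, s_hat, length.out = 101)
  C0 <- 1.58 * p$c0
  # uniform bonds, flat membrane: no flux, interface at rest
  expect_equal(interface_velocity(s, rep(C0, 101), numeric(101), p), 0)
  # manufactured linear profile c1 = C0 (1 + 0.1 s / s_hat), h = 0:
  # v_hat = -0.1 D1 / (1.1 s_hat)
  c1 <- C0 * (1 + 0.1 * s / s_hat)
  v <- interface_velocity(s, c1, numeric(101), p)
  expect_rel_equal(v, -0.1 * p$D1 / (1.1 * s_hat), 1e-10)
  # a stretch gradient alone also drives the interface
  xg <- sqrt(p$kBT / p$k)
  h <- xg * (s / s_hat)
  v_h <- interface_velocity(s, rep(C0, 101), h, p)
  expect_rel_equal(v_h, -p$D1 * 2 / s_hat, 1e-6)
  expect_error(interface_velocity(s, c(rep(C0, 100), 0), numeric(101), p),
               "zero")
})

test_that("prepared equilibrium is a fixed point of the coupled dynamics", {
  p <- regime_params("diffusion")   # reactions off, non-compliant
  eq <- prepare_equilibrium(p)
  scl <- derive_scales(p, c1ref = eq$c1_eq, gamma = eq$gamma_eq)
  tr <- run_peeling(p, t_end = 10 * scl$tau_diff1, resolution = 2)
  expect_lt(max(abs(tr$s_hat - p$s_hat0)) / p$s_hat0, 1e-6)
  expect_lt(max(abs(tr$v_hat)) * scl$tau_diff1 / p$s_hat0, 1e-5)
})

test_that("constant-theta Stefan runs track the similarity solution", {
  errs <- c()
  lams <- c()
  for (U in c(1.5, 2, 3)) {
    fx <- stefan_run(U)
    tr <- fx$traj
    lam <- lambda_of_U(U)
    tau <- tr$t / fx$scl$tau_diff1
    s_exact <- fx$params$s_hat0 * (1 + 2 * lam * sqrt(tau))
    rel <- abs(tr$s_hat - s_exact) / s_exact
    expect_lt(max(rel), 0.02)
    # similarity collapse of the concentration profiles
    cc <- similarity_collapse(tr, U)
    expect_lt(cc$max_dev, 0.03)
    # fitted similarity constant from the interface track
    sel <- tau > 0.005
    lam_fit <- stats::coef(stats::lm(
      I(tr$s_hat[sel] / fx$params$s_hat0 - 1) ~ 0 + I(2 * sqrt(tau[sel]))))
    lams <- c(lams, abs(lam_fit))
    errs <- c(errs, max(rel))
  }
  # |lambda| (fitted) increases with the driving parameter
  expect_true(all(diff(lams) > 0))
})

test_that("Stefan error decreases under mesh/timestep refinement", {
  U <- 2
  fine <- stefan_run(U)            # resolution 1
  coarse <- stefan_run(U, resolution = 4)
  lam <- lambda_of_U(U)
  err_of <- function(fx) {
    tau <- fx$traj$t / fx$scl$tau_diff1
    sel <- tau > 0.002
    s_exact <- fx$params$s_hat0 * (1 + 2 * lam * sqrt(tau[sel]))
    max(abs(fx$traj$s_hat[sel] - s_exact) / s_exact)
  }
  expect_lt(err_of(fine), err_of(coarse))
})

test_that("binders are conserved to near machine precision in every regime", {
  drift <- function(tr) {
    tot <- tr$N1 + tr$N2
    (max(tot) - min(tot)) / tot[1]
  }
  # diffusion regime (reactions off): bonds alone are exactly conserved
  tr_d <- stefan_run(2)$traj
  expect_lt((max(tr_d$N1) - min(tr_d$N1)) / tr_d$N1[1], 1e-12)
  expect_lt(drift(tr_d), 1e-9)
  # reaction-dominated travelling front (slip bonds, compliant)
  tr_r <- front_run(32)
  expect_lt(drift(tr_r), 1e-9)
  # mixed regime with capillary coupling
  fx_m <- fixture("mixed_short", function() {
    run_peeling(regime_params("mixed", F_over_gamma = 0.4), t_end = 50,
                resolution = 3, step_tol = 0.04)
  })
  expect_lt(drift(fx_m), 1e-9)
  # crowded mixed regime
  tr_c <- crowding_run(5, 400)
  expect_lt(drift(tr_c), 1e-9)
})

test_that("diffusion-dominated peeling self-stabilizes at a new equilibrium", {
  fx <- fixture("diff_F02", function() {
    p <- regime_params("diffusion", F_over_gamma = 0.2)
    scl <- derive_scales(p, c1ref = 1.58 * p$c0,
                         gamma = prepare_equilibrium(p)$gamma_eq)
    run_peeling(p, t_end = 12 * scl$tau_diff1, resolution = 2,
                snap_times = 12 * scl$tau_diff1)
  })
  n <- length(fx$t)
  # patch shrank, then arrested
  expect_lt(fx$s_hat[n], 0.95 * fx$params$s_hat0)
  tail_idx <- fx$t > 0.8 * fx$t[n]
  drift <- (max(fx$s_hat[tail_idx]) - min(fx$s_hat[tail_idx])) / fx$s_hat[n]
  expect_lt(drift, 1e-4)
  # uniform bond chemical potential at the final state (equilibrium), and
  # the interface force balance holds there
  sn <- fx$snapshots[[length(fx$snapshots)]]
  spread <- (max(sn$c1) - min(sn$c1)) / mean(sn$c1)
  expect_lt(spread, 1e-3)
  resid <- abs(fx$params$kBT * sn$c1[length(sn$c1)] -
               2 * fx$gamma * (1 - cos(sn$theta))) /
    (2 * fx$gamma * (1 - cos(sn$theta)))
  expect_lt(resid, 1e-2)
  # the patch is denser than at preparation (self-stabilizing concentration)
  expect_gt(mean(sn$c1), 1.58 * fx$params$c0)
})

test_that("trajectory CSV export writes scalar series and kymographs", {
  fx <- stefan_run(2)
  stem <- file.path(tempdir(), "traj_test")
  files <- write_trajectory_csv(fx$traj, stem)
  expect_true(all(file.exists(files)))
  sc <- utils::read.csv(paste0(stem, "_scalars.csv"))
  expect_equal(nrow(sc), length(fx$traj$t))
  expect_true(all(c("t", "s_hat", "v_hat", "N1") %in% names(sc)))
  ky <- utils::read.csv(paste0(stem, "_kymo_c1.csv"))
  expect_equal(length(unique(ky$t)), length(fx$traj$snapshots))
  unlink(files)
})
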