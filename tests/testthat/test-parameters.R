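test_that("derived scales reproduce their closed forms and printed values", {
  p <- peel_params(D1 = 0.25e-12)
  eq <- prepare_equilibrium(p)
  scl <- derive_scales(p, c1ref = eq$c1_eq, gamma = eq$gamma_eq)

  # patch diffusion time: s_hat0^2 / D1 = 25 s
  expect_equal(scl$tau_diff1, 25, tolerance = 1e-12)
  # vesicle-to-patch diffusion time ratio (L0/s0)^2 * D1/D2 = 98
  expect_equal(scl$tau_diff2 / scl$tau_diff1, 98, tolerance = 1e-12)
  expect_rel_equal(scl$tau_diff2 / scl$tau_diff1, 100, 0.05)

  # process-zone scales at reduced diffusivity
  p_slow <- peel_params(D1 = 0.25e-15, koff_bar = 10)
  scl_s <- derive_scales(p_slow, c1ref = eq$c1_eq, gamma = eq$gamma_eq)
  expect_equal(scl_s$l3, 5e-9, tolerance = 1e-12)
  expect_equal(scl_s$v0, 5e-8, tolerance = 1e-12)

  # entropic force and fluctuation scales
  expect_rel_equal(scl$f_gamma, 1.0e-12, 0.02)
  expect_equal(scl$f_gamma, sqrt(p$k * p$kBT), tolerance = 1e-14)
  expect_equal(scl$x_gamma, sqrt(p$kBT / p$k), tolerance = 1e-14)
  expect_rel_equal(scl$x_gamma, 4.05e-9, 0.01)

  # capillary length at the prepared tension is about 20 nm
  expect_rel_equal(scl$l1, 20e-9, 0.05)
  # foundation boundary layer at the reference bond density
  scl4 <- derive_scales(p, c1ref = 4e15, gamma = eq$gamma_eq)
  expect_equal(scl4$l2, (4 * p$kappa / (p$k * 4e15))^(1 / 4),
               tolerance = 1e-14)
  expect_rel_equal(scl4$l2, 25e-9, 0.01)

  # Damkohler ratio identity
  expect_equal(scl$Da2 / scl$Da1,
               (p$L0 / p$s_hat0)^2 * (p$D1 / p$D2), tolerance = 1e-12)
})

test_that("rate coefficients derive from the equilibrium constant", {
  p <- peel_params(Kbar = 2, koff_bar = 10)
  rc <- derive_rate_coefficients(p)
  expect_equal(rc$kon_bar, 20 / p$c0, tolerance = 1e-14)

  # ideal bonds: infinite separation sensitivity, flat off-rate
  p_ideal <- peel_params(f_beta = Inf, koff_bar = 10)
  expect_identical(derive_rate_coefficients(p_ideal)$x_beta, Inf)
  kf <- rate_functions(c(-5e-9, 0, 5e-9), p_ideal)
  expect_equal(kf$koff, rep(10, 3))

  # slip bonds at f_beta = 4 f_gamma
  f_gamma <- sqrt(p$k * p$kBT)
  p_slip <- peel_params(f_beta = 4 * f_gamma)
  xb <- derive_rate_coefficients(p_slip)$x_beta
  expect_equal(xb, 4 * f_gamma / p$k, tolerance = 1e-14)
  expect_rel_equal(xb, 16.2e-9, 0.01)
})

test_that("scales transform with their dimensional exponents under rescaling", {
  p <- peel_params(koff_bar = 10)
  eq <- prepare_equilibrium(p)
  scl <- derive_scales(p, c1ref = eq$c1_eq, gamma = eq$gamma_eq)
  set.seed(42)
  for (i in 1:5) {
    lam <- exp(stats::runif(1, -1, 1))
    # rescale all energies by lam (kBT, kappa) at fixed lengths/times:
    # l2 ~ kappa^(1/4) k^(-1/4); with k in N/m also an energy/length^2,
    # scale k by lam too so l2, x_gamma are invariant and f_gamma ~ lam
    p2 <- peel_params(kBT = p$kBT * lam, kappa = p$kappa * lam,
                      k = p$k * lam, koff_bar = 10)
    s2 <- derive_scales(p2, c1ref = eq$c1_eq, gamma = eq$gamma_eq * lam)
    expect_equal(s2$l1, scl$l1, tolerance = 1e-12)
    expect_equal(s2$l2, scl$l2, tolerance = 1e-12)
    expect_equal(s2$x_gamma, scl$x_gamma, tolerance = 1e-12)
    expect_equal(s2$f_gamma, scl$f_gamma * lam, tolerance = 1e-12)
    # rescale all times by lam: diffusivities 1/lam, rates 1/lam
    p3 <- peel_params(D1 = p$D1 / lam, D2 = p$D2 / lam,
                      koff_bar = 10 / lam)
    s3 <- derive_scales(p3, c1ref = eq$c1_eq, gamma = eq$gamma_eq)
    expect_equal(s3$tau_diff1, scl$tau_diff1 * lam, tolerance = 1e-12)
    expect_equal(s3$tau_reac, scl$tau_reac * lam, tolerance = 1e-12)
    expect_equal(s3$l3, scl$l3, tolerance = 1e-12)
    expect_equal(s3$v0, scl$v0 / lam, tolerance = 1e-12)
    expect_equal(s3$Da1, scl$Da1, tolerance = 1e-12)
  }
})

test_that("parameter validation names the offending field", {
  expect_error(peel_params(kBT = -1), "kBT")
  expect_error(peel_params(s_hat0 = 11e-6), "s_hat0")
  expect_error(peel_params(alpha = 0.9), "alpha")
  expect_error(peel_params(F_over_gamma = 2.5), "F_over_gamma")
  expect_error(peel_params(crowding = TRUE, cmax = Inf), "cmax")
  expect_error(derive_scales(peel_params(), c1ref = -1), "c1ref")
  # (alpha - 1) * s_hat0 must exceed the capillary length
  expect_error(peel_params(gamma = 1e-9, alpha = 1.01), "alpha")
})

test_that("config files reject unknown sections and keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  Kbar: 2.0", "modes:",
               "  regime: diffusion"), f)
  cfg <- read_peel_config(f)
  expect_s3_class(cfg$params, "peel_params")
  expect_false(cfg$params$reactions_on)
  writeLines(c("parameters:", "  Kbar: 2.0", "  bogus_key: 1"), f)
  expect_error(read_peel_config(f), "bogus_key")
  writeLines(c("mystery_section:", "  a: 1"), f)
  expect_error(read_peel_config(f), "mystery_section")
  unlink(f)
})
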