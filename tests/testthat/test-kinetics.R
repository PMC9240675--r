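test_that("chemical potentials: reference state, stretching term, crowded limit", {
  p <- peel_params()
  xg <- sqrt(p$kBT / p$k)
  # reference state mu1(c0, h=0) = 0
  pot <- chemical_potentials(p$c0, p$c0, 0, p)
  expect_equal(pot$mu1, 0, tolerance = 1e-15)
  expect_equal(pot$mu2, p$kBT * log(p$Kbar) / 2, tolerance = 1e-15)
  # stretching by x_gamma adds exactly kBT
  pot_s <- chemical_potentials(p$c0, p$c0, xg, p)
  expect_equal(pot_s$mu1 - pot$mu1, p$kBT, tolerance = 1e-12)
  # depleted bonds yield the -Inf sentinel, not an arithmetic error
  expect_identical(chemical_potentials(0, p$c0, 0, p)$mu1, -Inf)
  # crowded potentials approach the dilute ones as cmax grows
  p_cr <- peel_params(crowding = TRUE, cmax = 500 * p$c0)
  pot_cr <- chemical_potentials(1.5 * p$c0, 0.9 * p$c0, 0, p_cr)
  pot_di <- chemical_potentials(1.5 * p$c0, 0.9 * p$c0, 0, p)
  expect_lt(abs(pot_cr$mu1 - pot_di$mu1) / p$kBT, 0.01)
  # difference is O(c/cmax)
  p_cr2 <- peel_params(crowding = TRUE, cmax = 5000 * p$c0)
  pot_cr2 <- chemical_potentials(1.5 * p$c0, 0.9 * p$c0, 0, p_cr2)
  expect_rel_equal(pot_cr$mu1 - pot_di$mu1,
                   10 * (pot_cr2$mu1 - pot_di$mu1), 0.05)
  # overflow is a hard error
  p_cr5 <- peel_params(crowding = TRUE, cmax = 5 * p$c0)
  expect_error(chemical_potentials(3 * p$c0, 2.5 * p$c0, 0, p_cr5),
               "crowding overflow")
  # monotonicity in c1 and |h|
  cs <- seq(0.1, 3, length.out = 20) * p$c0
  mus <- chemical_potentials(cs, p$c0, 0, p)$mu1
  expect_true(all(diff(mus) > 0))
  hs <- seq(0, 5 * xg, length.out = 20)
  mus_h <- chemical_potentials(p$c0, p$c0, hs, p)$mu1
  expect_true(all(diff(mus_h) > 0))
})

test_that("rate laws: e-folding scales and the K(h) identity", {
  f_gamma <- sqrt(2.5e-4 * 4.11e-21)
  p <- peel_params(f_beta = 4 * f_gamma, koff_bar = 10)
  rc <- derive_rate_coefficients(p)
  r0 <- rate_functions(0, p)
  expect_equal(r0$kon, rc$kon_bar, tolerance = 1e-14)
  expect_equal(r0$koff, p$koff_bar, tolerance = 1e-14)
  expect_rel_equal(rate_functions(rc$x_beta, p)$koff, exp(1) * p$koff_bar,
                   1e-12)
  expect_rel_equal(rate_functions(rc$x_gamma, p)$kon, rc$kon_bar / exp(1),
                   1e-12)
  # compression slows unbinding (signed Bell exponent)
  expect_lt(rate_functions(-rc$x_beta, p)$koff, p$koff_bar)
  # separation-dependent equilibrium constant for ideal bonds:
  # c0 * kon(h) / koff = Kbar * exp(-(h/x_gamma)^2)
  p_id <- peel_params(f_beta = Inf, koff_bar = 10)
  hs <- seq(-2, 2, length.out = 9) * rc$x_gamma
  r <- rate_functions(hs, p_id)
  expect_equal(p_id$c0 * r$kon / r$koff,
               p_id$Kbar * exp(-(hs / rc$x_gamma)^2), tolerance = 1e-12)
})

test_that("osmotic tension: dilute and crowded forms, limits, Gibbs-Duhem", {
  p <- peel_params()
  eq <- prepare_equilibrium(p)
  # dilute van't Hoff at the prepared state
  expect_rel_equal(osmotic_tension(eq$c1_eq, p), 1.62e-5, 0.005)
  # printed estimate at c1 = 4e3 um^-2
  expect_rel_equal(osmotic_tension(4e15, p), 1.6e-5, 0.03)
  p_cr <- peel_params(crowding = TRUE, cmax = 10 * p$c0)
  # closed-form crowded value at c1 = 0.1 cmax
  Pi_cr <- osmotic_tension(0.1 * p_cr$cmax, p_cr)
  expect_rel_equal(Pi_cr / (p$kBT * p_cr$cmax), 0.1107210, 1e-4)
  # van't Hoff limit as c1/cmax -> 0
  expect_rel_equal(osmotic_tension(1e-3 * p_cr$cmax, p_cr),
                   p$kBT * 1e-3 * p_cr$cmax, 2e-3)
  # monotone increasing, divergent toward cmax
  cs <- seq(0.05, 0.95, length.out = 30) * p_cr$cmax
  expect_true(all(diff(osmotic_tension(cs, p_cr)) > 0))
  expect_error(osmotic_tension(p_cr$cmax, p_cr), "saturation")
  # Gibbs-Duhem: integral of c1 dmu1/dc1 (c2 = 0, h = 0) reproduces Pi
  c1_top <- 0.6 * p_cr$cmax
  dmu1_dc1 <- function(c1) {
    p$kBT * (1 / c1 + 2 / (p_cr$cmax - c1))
  }
  Pi_gd <- stats::integrate(function(c1) c1 * dmu1_dc1(c1), 0, c1_top,
                            rel.tol = 1e-12)$value
  expect_rel_equal(Pi_gd, osmotic_tension(c1_top, p_cr), 1e-8)
})

test_that("detailed balance: reaction equilibrium equals mu1 = 2 mu2", {
  p <- peel_params(f_beta = Inf, koff_bar = 10)
  rc <- derive_rate_coefficients(p)
  for (h in c(0, rc$x_gamma, 2 * rc$x_gamma)) {
    r <- rate_functions(h, p)
    # pick c2, then c1 from local reaction equilibrium
    c2 <- 0.7 * p$c0
    c1 <- r$kon * c2^2 / r$koff
    pot <- chemical_potentials(c1, c2, h, p)
    expect_lt(abs(pot$mu1 - 2 * pot$mu2) / p$kBT, 1e-10)
  }
  # the identity survives crowding with the two-site bond footprint
  p_cr <- peel_params(f_beta = Inf, koff_bar = 10, crowding = TRUE,
                      cmax = 5 * 2.5e15)
  r <- rate_functions(0, p_cr)
  c2 <- 0.7 * p_cr$c0
  c1 <- r$kon * c2^2 / r$koff
  pot <- chemical_potentials(c1, c2, 0, p_cr)
  expect_lt(abs(pot$mu1 - 2 * pot$mu2) / p_cr$kBT, 1e-10)
})

test_that("interface concentration inverts the force balance in both modes", {
  p <- peel_params()
  eq <- prepare_equilibrium(p)
  # prepared state consistency: c1(s_hat) = C0
  c1g <- interface_concentration(list(theta = eq$theta0), eq$gamma_eq, p)
  expect_rel_equal(c1g, eq$C0, 1e-12)
  # dilute linearity in (1 - cos theta): U = 2 doubles it
  theta2 <- acos(1 - 2 * (1 - cos(eq$theta0)))
  c1g2 <- interface_concentration(list(theta = theta2), eq$gamma_eq, p)
  expect_rel_equal(c1g2, 2 * eq$C0, 1e-12)
  # crowded: against an independent bisection oracle of the closed form
  p_cr <- peel_params(crowding = TRUE, cmax = 5 * p$c0)
  target <- p$kBT * 3 * p$c0
  theta_t <- acos(1 - target / (2 * eq$gamma_eq))
  c1_cr <- interface_concentration(list(theta = theta_t), eq$gamma_eq, p_cr)
  oracle <- uniroot(function(c1) {
    -p$kBT * (2 * p_cr$cmax * log((p_cr$cmax - c1) / p_cr$cmax) + c1) - target
  }, c(0, p_cr$cmax * (1 - 1e-12)), tol = 1e-6)$root
  expect_rel_equal(c1_cr, oracle, 1e-7)
  # crowded value sits below the dilute one (crowding supplies extra tension)
  expect_lt(c1_cr, 3 * p$c0)
})
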