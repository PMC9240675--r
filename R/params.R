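#' Model parameters for membrane-peeling simulations
#'
#' Collects all physical, kinetic and geometric constants of the coupled
#' mechano-chemical peeling model, together with mode switches. Units are SI
#' (m, s, J, N/m). The one-dimensional membrane is a ribbon of depth
#' \code{l_lat}; with the default \code{l_lat = 1e-6} m, two-dimensional
#' number densities in molecules/um^2 map numerically 1:1 onto the model's
#' per-unit-depth line densities, so concentrations are stored as areal
#' densities in molecules/m^2.
#'
#' @param kBT thermal energy, J.
#' @param kappa membrane bending stiffness, J (per unit depth).
#' @param gamma membrane tension, N/m, or \code{NULL} to derive it during
#'   equilibrium preparation from the Young-Dupre balance.
#' @param k bond extensional stiffness, N/m.
#' @param f_beta slip-bond force sensitivity, N; \code{Inf} for ideal
#'   (force-insensitive) bonds.
#' @param D1 bond diffusivity, m^2/s.
#' @param D2 free-binder diffusivity, m^2/s. Defaults to \code{2 * D1}: a
#'   bond connects one binder on each membrane, so its mobility is half that
#'   of a free binder.
#' @param koff_bar unstressed off-rate, 1/s. Set to 0 (with
#'   \code{reactions_on = FALSE}) for the diffusion-dominated regime.
#' @param Kbar non-dimensional two-dimensional equilibrium constant.
#'   The binding rate is always derived from it as
#'   \code{kon_bar = Kbar * koff_bar / c0}, never set independently.
#' @param c0 reference binder concentration, molecules/m^2.
#' @param cmax crowding saturation concentration, molecules/m^2;
#'   \code{Inf} selects the dilute model.
#' @param R0 initial vesicle radius, m.
#' @param s_hat0 initial adhesion-patch half-size, m.
#' @param L0 half-vesicle membrane length, m.
#' @param F_over_gamma applied vertical force as a fraction of tension.
#' @param l_lat ribbon depth, m.
#' @param alpha micro-mechanical domain factor (> 1): the separation profile
#'   is solved on [0, alpha * s_hat] so the far boundary is unaffected by
#'   bending; results are insensitive to this value.
#' @param compliant logical; resolve bond stretching h(x) through the
#'   micro-mechanical model. \code{FALSE} sets h = 0 everywhere (this is not
#'   the stiff limit of the compliant model).
#' @param crowding logical; use Flory-Huggins crowded thermodynamics.
#' @param reactions_on logical; enable binding/unbinding kinetics.
#' @param constant_theta logical; hold the contact angle fixed at its value
#'   just after force application instead of re-solving vesicle capillarity,
#'   reproducing the analytic Stefan / travelling-front assumption.
#'
#' @return An object of class \code{peel_params} (a validated named list).
#' @examples
#' p <- peel_params()
#' derive_scales(p, c1ref = 4e15)
#' @export
peel_params <- function(kBT = 4.11e-21,
                        kappa = 1e-19,
                        gamma = NULL,
                        k = 2.5e-4,
                        f_beta = Inf,
                        D1 = 0.25e-12,
                        D2 = 2 * D1,
                        koff_bar = 10,
                        Kbar = 2,
                        c0 = 2.5e15,
                        cmax = Inf,
                        R0 = 10e-6,
                        s_hat0 = 2.5e-6,
                        L0 = 35e-6,
                        F_over_gamma = 0,
                        l_lat = 1e-6,
                        alpha = 1.3,
                        compliant = FALSE,
                        crowding = FALSE,
                        reactions_on = TRUE,
                        constant_theta = FALSE) {
  p <- list(kBT = kBT, kappa = kappa, gamma = gamma, k = k, f_beta = f_beta,
            D1 = D1, D2 = D2, koff_bar = koff_bar, Kbar = Kbar, c0 = c0,
            cmax = cmax, R0 = R0, s_hat0 = s_hat0, L0 = L0,
            F_over_gamma = F_over_gamma, l_lat = l_lat, alpha = alpha,
            compliant = isTRUE(compliant), crowding = isTRUE(crowding),
            reactions_on = isTRUE(reactions_on),
            constant_theta = isTRUE(constant_theta))
  class(p) <- "peel_params"
  validate_peel_params(p)
}

#' Validate a parameter set
#'
#' Checks positivity, geometric consistency and mode coherence; called by
#' \code{\link{peel_params}} and again by the solvers on entry.
#'
#' @param p a \code{peel_params} object.
#' @return \code{p}, invisibly checked.
#' @export
validate_peel_params <- function(p) {
  stopifnot(inherits(p, "peel_params"))
  for (f in c("kBT", "kappa", "k", "D1", "D2", "c0", "R0", "s_hat0",
              "L0", "l_lat")) {
    check_positive(p[[f]], f)
  }
  check_positive(p$f_beta, "f_beta", allow_inf = TRUE)
  check_positive(p$cmax, "cmax", allow_inf = TRUE)
  if (!is.numeric(p$Kbar) || p$Kbar < 0) fail_field("Kbar", "must be >= 0")
  if (!is.numeric(p$koff_bar) || p$koff_bar < 0) {
    fail_field("koff_bar", "must be >= 0")
  }
  if (!is.null(p$gamma)) check_positive(p$gamma, "gamma")
  if (!is.numeric(p$F_over_gamma) || p$F_over_gamma < 0 ||
      p$F_over_gamma >= 2) {
    fail_field("F_over_gamma", "must lie in [0, 2): tension cannot balance the load otherwise")
  }
  if (p$alpha <= 1) fail_field("alpha", "must be > 1")
  if (p$s_hat0 >= p$R0) fail_field("s_hat0", "must be < R0 so sin(theta0) = s_hat0/R0 is defined")
  if (p$s_hat0 >= p$L0) fail_field("s_hat0", "must be < L0")
  if (!is.null(p$gamma)) {
    l1 <- sqrt(p$kappa / p$gamma)
    if ((p$alpha - 1) * p$s_hat0 <= l1) {
      fail_field("alpha", sprintf(
        "(alpha - 1) * s_hat0 = %.3g m must exceed l1 = %.3g m",
        (p$alpha - 1) * p$s_hat0, l1))
    }
  }
  if (p$crowding && !is.finite(p$cmax)) {
    fail_field("cmax", "must be finite in crowding mode")
  }
  invisible(p)
}

#' Derived molecular and dynamical scales
#'
#' Evaluates the closed-form length, force and time scales of the model:
#' the capillary/bending length l1 = sqrt(kappa/gamma), the elastic-foundation
#' boundary-layer length l2 = (4 kappa / (k c1))^(1/4), the process-zone
#' length l3 = sqrt(D1/koff_bar), the front-speed scale v0 =
#' sqrt(D1 * koff_bar), the entropic force scale f_gamma = sqrt(k kBT), the
#' thermal-fluctuation scale x_gamma = sqrt(kBT/k), the separation
#' sensitivity x_beta = f_beta/k, diffusive and reactive time scales and
#' their Damkohler ratios, and the interface bond-concentration scale
#' C0 = 2 gamma (1 - cos(theta0)) / kBT.
#'
#' @param params a \code{\link{peel_params}} object.
#' @param c1ref reference bond concentration, molecules/m^2, used for l2.
#' @param gamma membrane tension, N/m, used for l1 and C0; defaults to
#'   \code{params$gamma}. Either may be \code{NULL}, in which case the
#'   gamma-dependent scales are returned as \code{NA}.
#' @return An object of class \code{peel_scales}, a named list of scales
#'   in SI units.
#' @examples
#' p <- peel_params(D1 = 0.25e-15, koff_bar = 10)
#' s <- derive_scales(p, c1ref = 4e15)
#' s$l3   # 5e-9 m
#' s$v0   # 5e-8 m/s
#' @export
derive_scales <- function(params, c1ref, gamma = params$gamma) {
  validate_peel_params(params)
  check_positive(c1ref, "c1ref")
  kBT <- params$kBT
  k <- params$k
  theta0 <- asin(params$s_hat0 / params$R0)
  sc <- list(
    l1 = if (is.null(gamma)) NA_real_ else sqrt(params$kappa / gamma),
    l2 = (4 * params$kappa / (k * c1ref))^(1 / 4),
    l3 = if (params$koff_bar > 0) sqrt(params$D1 / params$koff_bar) else Inf,
    v0 = sqrt(params$D1 * params$koff_bar),
    f_gamma = sqrt(k * kBT),
    x_gamma = sqrt(kBT / k),
    x_beta = params$f_beta / k,
    tau_diff1 = params$s_hat0^2 / params$D1,
    tau_diff2 = params$L0^2 / params$D2,
    tau_reac = if (params$koff_bar > 0) 1 / params$koff_bar else Inf,
    kon_bar = params$Kbar * params$koff_bar / params$c0,
    theta0 = theta0,
    C0 = if (is.null(gamma)) NA_real_ else
      2 * gamma * (1 - cos(theta0)) / kBT
  )
  sc$Da1 <- sc$tau_diff1 / sc$tau_reac
  sc$Da2 <- sc$tau_diff2 / sc$tau_reac
  class(sc) <- "peel_scales"
  sc
}

#' Rate coefficients derived from the equilibrium constant
#'
#' The binding rate is never an independent parameter: it follows from the
#' two-dimensional equilibrium constant as \code{kon_bar = Kbar * koff_bar /
#' c0}. Also returns the thermal-fluctuation scale \code{x_gamma =
#' sqrt(kBT/k)} and the Bell separation sensitivity \code{x_beta = f_beta/k}
#' (infinite for ideal bonds, making the off-rate separation-independent).
#'
#' @param params a \code{\link{peel_params}} object.
#' @return list with \code{kon_bar} (m^2/s), \code{x_gamma} (m),
#'   \code{x_beta} (m).
#' @export
derive_rate_coefficients <- function(params) {
  validate_peel_params(params)
  list(kon_bar = params$Kbar * params$koff_bar / params$c0,
       x_gamma = sqrt(params$kBT / params$k),
       x_beta = params$f_beta / params$k)
}

#' @export
print.peel_params <- function(x, ...) {
  cat("<peel_params>\n")
  um <- 1e6
  cat(sprintf("  kBT = %.3g J, kappa = %.3g J, k = %.3g N/m\n",
              x$kBT, x$kappa, x$k))
  cat(sprintf("  gamma = %s N/m, f_beta = %s N\n",
              if (is.null(x$gamma)) "derived at preparation"
              else sprintf("%.3g", x$gamma),
              format(x$f_beta)))
  cat(sprintf("  D1 = %.3g, D2 = %.3g um^2/s; koff_bar = %.3g 1/s; Kbar = %.3g\n",
              x$D1 * 1e12, x$D2 * 1e12, x$koff_bar, x$Kbar))
  cat(sprintf("  c0 = %.3g um^-2, cmax = %s um^-2\n",
              x$c0 / 1e12, format(x$cmax / 1e12)))
  cat(sprintf("  R0 = %.3g, s_hat0 = %.3g, L0 = %.3g um; F/gamma = %.3g\n",
              x$R0 * um, x$s_hat0 * um, x$L0 * um, x$F_over_gamma))
  cat(sprintf("  modes: compliant=%s crowding=%s reactions=%s constant_theta=%s\n",
              x$compliant, x$crowding, x$reactions_on, x$constant_theta))
  invisible(x)
}

#' @export
print.peel_scales <- function(x, ...) {
  cat("<peel_scales>\n")
  nm <- 1e9
  fmt <- function(v, unit, f = 1) {
    if (is.na(v)) "NA" else sprintf("%.4g %s", v * f, unit)
  }
  cat("  l1 (capillary/bending)   ", fmt(x$l1, "nm", nm), "\n")
  cat("  l2 (foundation layer)    ", fmt(x$l2, "nm", nm), "\n")
  cat("  l3 (process zone)        ", fmt(x$l3, "nm", nm), "\n")
  cat("  v0 (front-speed scale)   ", fmt(x$v0, "nm/s", nm), "\n")
  cat("  f_gamma (entropic force) ", fmt(x$f_gamma, "pN", 1e12), "\n")
  cat("  x_gamma, x_beta          ", fmt(x$x_gamma, "nm", nm), ",",
      fmt(x$x_beta, "nm", nm), "\n")
  cat("  tau_diff1, tau_diff2     ", fmt(x$tau_diff1, "s"), ",",
      fmt(x$tau_diff2, "s"), "\n")
  cat("  tau_reac                 ", fmt(x$tau_reac, "s"), "\n")
  cat("  Da1, Da2                 ", fmt(x$Da1, ""), ",", fmt(x$Da2, ""), "\n")
  cat("  C0 (interface conc.)     ", fmt(x$C0, "um^-2", 1e-12), "\n")
  invisible(x)
}
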