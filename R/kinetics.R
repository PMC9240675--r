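# Chemical potentials, separation-dependent rate laws and osmotic tension,
# in dilute and crowded (Flory-Huggins) variants. All pure functions.

#' Chemical potentials of bonds and free binders
#'
#' Dilute: \code{mu1 = mu1_0 + kBT*log(c1/c0) + kBT*(h/x_gamma)^2},
#' \code{mu2 = mu2_0 + kBT*log(c2/c0)}. In crowding mode a Flory-Huggins
#' vacancy term is added: bonds occupy two lattice sites (one binder on each
#' membrane leaflet projects onto the same patch footprint), free binders
#' one, giving \code{mu1} an extra \code{-2*kBT*log((cmax - c1 - c2)/cmax)}
#' and \code{mu2} an extra \code{-kBT*log((cmax - c1 - c2)/cmax)}.
#'
#' \code{mu1_0 = 0} by convention; \code{mu2_0 = kBT*log(Kbar)/2}.
#'
#' @param c1 bond concentration(s), molecules/m^2.
#' @param c2 free-binder concentration(s), molecules/m^2.
#' @param h local separation(s) from the unstressed bond length, m.
#' @param params a \code{\link{peel_params}} object.
#' @param mu2_vacancy logical; include the single-site vacancy term in mu2
#'   (crowding mode only).
#' @return list with vectors \code{mu1}, \code{mu2} in J. \code{c1 = 0}
#'   yields \code{mu1 = -Inf} as a sentinel.
#' @export
chemical_potentials <- function(c1, c2, h, params, mu2_vacancy = TRUE) {
  kBT <- params$kBT
  c0 <- params$c0
  xg <- sqrt(kBT / params$k)
  mu1_0 <- 0
  mu2_0 <- if (params$Kbar > 0) kBT * log(params$Kbar) / 2 else -Inf
  stopifnot(all(c1 >= 0), all(c2 >= 0))
  stretch <- kBT * (h / xg)^2
  mu1 <- ifelse(c1 > 0, mu1_0 + kBT * log(c1 / c0) + stretch, -Inf)
  mu2 <- ifelse(c2 > 0, mu2_0 + kBT * log(c2 / c0), -Inf)
  if (params$crowding) {
    vac <- (params$cmax - c1 - c2) / params$cmax
    if (any(vac <= 0)) {
      stop("crowding overflow: c1 + c2 must stay strictly below cmax",
           call. = FALSE)
    }
    mu1 <- mu1 - 2 * kBT * log(vac)
    if (mu2_vacancy) mu2 <- mu2 - kBT * log(vac)
  }
  list(mu1 = mu1, mu2 = mu2)
}

#' Separation-dependent binding and unbinding rates
#'
#' Binding slows as the membranes separate because thermally fluctuating
#' partners meet less often: \code{kon(h) = kon_bar * exp(-(h/x_gamma)^2)}.
#' Unbinding follows the Bell slip-bond law \code{koff(h) = koff_bar *
#' exp(h / x_beta)} with \code{x_beta = f_beta / k}; the exponent is signed,
#' so compression (h < 0) slows unbinding. Ideal bonds (\code{f_beta = Inf})
#' have \code{koff = koff_bar} at all separations.
#'
#' @param h separation(s), m.
#' @param params a \code{\link{peel_params}} object.
#' @return list with vectors \code{kon} (m^2/s) and \code{koff} (1/s).
#' @export
rate_functions <- function(h, params) {
  rc <- derive_rate_coefficients(params)
  kon <- rc$kon_bar * exp(-(h / rc$x_gamma)^2)
  koff <- if (is.finite(rc$x_beta)) {
    params$koff_bar * exp(h / rc$x_beta)
  } else {
    rep(params$koff_bar, length(h))
  }
  list(kon = kon, koff = koff)
}

#' Osmotic tension of the bond gas
#'
#' In the dilute limit the two-dimensional bond gas exerts the van't Hoff
#' tension \code{Pi = kBT * c1}. Near the crowding limit the Flory-Huggins
#' form \code{Pi = -kBT * (2 * cmax * log((cmax - c1)/cmax) + c1)} applies:
#' it is strictly increasing in c1, diverges as c1 -> cmax, and reduces to
#' van't Hoff for c1 << cmax.
#'
#' @param c1 bond concentration(s), molecules/m^2.
#' @param params a \code{\link{peel_params}} object; \code{params$crowding}
#'   selects the form.
#' @return osmotic tension, N/m (vectorized).
#' @export
osmotic_tension <- function(c1, params) {
  stopifnot(all(c1 >= 0))
  kBT <- params$kBT
  if (!params$crowding) return(kBT * c1)
  cmax <- params$cmax
  if (any(c1 >= cmax)) {
    stop("saturation error: c1 must stay strictly below cmax", call. = FALSE)
  }
  -kBT * (2 * cmax * log((cmax - c1) / cmax) + c1)
}

#' Interface bond concentration from the force balance
#'
#' The Young-Dupre balance at the moving patch edge requires the osmotic
#' tension of bonds to equal \code{2 * gamma * (1 - cos(theta))}. Dilute:
#' \code{c1(s_hat) = 2 gamma (1 - cos theta) / kBT} in closed form.
#' Crowded: the unique root of \code{Pi(c1) = 2 gamma (1 - cos theta)} in
#' [0, cmax), found by bracketed iteration to 1e-12 relative (the crowded
#' Pi diverges at cmax, so a root always exists).
#'
#' @param shape a \code{peel_shape} (or any list with \code{theta}).
#' @param gamma membrane tension, N/m.
#' @param params a \code{\link{peel_params}} object.
#' @return interface bond concentration, molecules/m^2. In crowding mode a
#'   warning reports near-saturation (c1 > 0.999 * cmax).
#' @export
interface_concentration <- function(shape, gamma, params) {
  target <- 2 * gamma * (1 - cos(shape$theta))
  if (!params$crowding) return(target / params$kBT)
  cmax <- params$cmax
  f <- function(c1) osmotic_tension(c1, params) - target
  hi <- cmax * (1 - 1e-14)
  r <- stats::uniroot(f, c(0, hi), tol = 1e-14 * cmax)
  c1 <- r$root
  # polish to 1e-12 relative via Newton on the closed form
  for (i in 1:20) {
    res <- osmotic_tension(c1, params) - target
    dPi <- params$kBT * (2 * cmax / (cmax - c1) - 1)
    step <- res / dPi
    if (abs(step) < 1e-13 * max(c1, params$c0)) break
    c1 <- min(max(c1 - step, 0), hi)
  }
  if (c1 > 0.999 * cmax) {
    warning("interface bond concentration within 0.1% of the crowding limit")
  }
  c1
}
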