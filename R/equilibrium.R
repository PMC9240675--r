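#' Equilibrium bond and free-binder concentrations
#'
#' Solves the two-equation preparation system: the law of mass action
#' \code{c0 * c1 / c2^2 = Kbar} together with conservation of the total
#' number of binders \code{c1 * s_hat0 + c2 * L0 = c0 * L0}. Eliminating c1
#' gives the quadratic \code{Kbar * s_hat0 * x^2 + L0 * x - L0 = 0} in
#' \code{x = c2/c0}, solved in closed form (unique non-negative root).
#'
#' @param params a \code{\link{peel_params}} object.
#' @return list with \code{c1_eq} and \code{c2_eq} in molecules/m^2.
#' @examples
#' eq <- equilibrium_concentrations(peel_params())
#' eq$c1_eq / peel_params()$c0   # 1.58
#' @export
equilibrium_concentrations <- function(params) {
  validate_peel_params(params)
  K <- params$Kbar
  s0 <- params$s_hat0
  L0 <- params$L0
  if (K == 0) {
    return(list(c1_eq = 0, c2_eq = params$c0))
  }
  a <- K * s0
  disc <- L0^2 + 4 * a * L0
  x <- (-L0 + sqrt(disc)) / (2 * a)   # c2 / c0, non-negative root
  if (x < 0) stop("internal error: no non-negative equilibrium root")
  list(c1_eq = K * x^2 * params$c0, c2_eq = x * params$c0)
}

#' Equilibrium membrane tension from the Young-Dupre balance
#'
#' At the prepared state the osmotic tension of the bonds balances the
#' membrane pull at the patch edge: \code{kBT * c1 = 2 * gamma * (1 -
#' cos(theta0))} with \code{theta0 = asin(s_hat0 / R0)}. Given the prepared
#' bond concentration this yields the tension.
#'
#' @param params a \code{\link{peel_params}} object.
#' @param c1_eq equilibrium bond concentration, molecules/m^2.
#' @return list with \code{gamma_eq} (N/m) and \code{theta0} (rad).
#' @export
equilibrium_tension <- function(params, c1_eq) {
  validate_peel_params(params)
  check_positive(c1_eq, "c1_eq")
  if (params$s_hat0 >= params$R0) {
    stop("geometry error: s_hat0 must be smaller than R0")
  }
  theta0 <- asin(params$s_hat0 / params$R0)
  gamma_eq <- params$kBT * c1_eq / (2 * (1 - cos(theta0)))
  list(gamma_eq = gamma_eq, theta0 = theta0)
}

#' Prepare the full equilibrium state
#'
#' Runs the closed-form preparation: equilibrium concentrations (mass action
#' + conservation), tension (Young-Dupre), contact angle, standard chemical
#' potentials (mu1_0 = 0 by convention, mu2_0 = kBT*log(Kbar)/2) and the
#' interface concentration scale C0 (equal to c1_eq at preparation).
#'
#' @param params a \code{\link{peel_params}} object.
#' @return object of class \code{peel_equilibrium}.
#' @export
prepare_equilibrium <- function(params) {
  conc <- equilibrium_concentrations(params)
  tens <- equilibrium_tension(params, conc$c1_eq)
  st <- list(
    c1_eq = conc$c1_eq, c2_eq = conc$c2_eq,
    gamma_eq = tens$gamma_eq, theta0 = tens$theta0,
    mu1_0 = 0,
    mu2_0 = if (params$Kbar > 0) params$kBT * log(params$Kbar) / 2 else -Inf,
    C0 = conc$c1_eq,
    Ntot = params$c0 * params$L0)
  class(st) <- "peel_equilibrium"
  st
}

#' @export
print.peel_equilibrium <- function(x, ...) {
  cat("<peel_equilibrium>\n")
  cat(sprintf("  c1_eq = %.4g um^-2, c2_eq = %.4g um^-2\n",
              x$c1_eq / 1e12, x$c2_eq / 1e12))
  cat(sprintf("  gamma_eq = %.4g N/m, theta0 = %.4g deg\n",
              x$gamma_eq, x$theta0 * 180 / pi))
  cat(sprintf("  mu2_0 = %.4g J, Ntot = %.4g (per l_lat)\n", x$mu2_0, x$Ntot))
  invisible(x)
}

# ---- vesicle capillary geometry -------------------------------------------

# Closed-form enclosed area of the two-dimensional vesicle whose free
# contour is, per symmetric half, a circular arc from the patch edge
# (s_hat, 0), leaving at tangent angle theta, to the apex on the symmetry
# axis, arriving at tangent angle pi - beta. Arc radius R =
# s_hat / (sin(theta) - sin(beta)). Both halves are counted.
vesicle_area <- function(s_hat, theta, beta, R) {
  a <- s_hat - R * sin(theta)
  b <- R * cos(theta)
  psi1 <- theta
  psi2 <- pi - beta
  half <- 0.5 * R * (a * (cos(psi1) - cos(psi2)) +
                     b * (sin(psi1) - sin(psi2)) +
                     R * (psi2 - psi1))
  2 * half
}

#' Quasi-static vesicle shape under tension and applied force
#'
#' Solves the vesicle-scale capillary problem: given tension \code{gamma},
#' vertical force \code{F} applied by the loading device at the apex, the
#' current patch half-size \code{s_hat} and the conserved enclosed area
#' \code{A0}, returns the contact angle \code{theta}, the apex load angle
#' \code{beta = asin(F / (2 gamma))} (two membrane leaves each pulling at
#' angle beta), the free-arc radius \code{R = s_hat / (sin(theta) -
#' sin(beta))} and the Laplace pressure \code{P = gamma / R}. The free
#' contour is a circular arc (uniform tension and pressure imply constant
#' curvature); \code{theta} is the root of the area-closure equation,
#' bracketed and polished to |dA|/A0 < 1e-12.
#'
#' @param gamma membrane tension, N/m.
#' @param F applied force per unit depth, N/m (i.e. \code{F_over_gamma *
#'   gamma}).
#' @param s_hat current patch half-size, m.
#' @param A0 conserved enclosed area, m^2 (see \code{\link{reference_area}}).
#' @return object of class \code{peel_shape} with fields \code{s_hat},
#'   \code{theta}, \code{beta}, \code{R}, \code{P}, \code{A0}.
#' @examples
#' A0 <- reference_area(2.5e-6, 10e-6)
#' solve_vesicle_shape(2.55e-4, 0, 2.5e-6, A0)
#' @export
solve_vesicle_shape <- function(gamma, F, s_hat, A0) {
  check_positive(gamma, "gamma")
  check_positive(s_hat, "s_hat")
  check_positive(A0, "A0")
  if (F < 0 || F >= 2 * gamma) {
    stop("tension cannot balance load: require 0 <= F < 2*gamma",
         call. = FALSE)
  }
  beta <- asin(F / (2 * gamma))
  area_of_theta <- function(theta) {
    R <- s_hat / (sin(theta) - sin(beta))
    vesicle_area(s_hat, theta, beta, R)
  }
  lo <- beta + 1e-9
  hi <- pi / 2 - 1e-12
  f <- function(th) area_of_theta(th) - A0
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop("geometry-infeasible: no contact angle in (beta, pi/2) encloses A0",
         call. = FALSE)
  }
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-15)
  theta <- r$root
  # secant polish on the area residual
  for (i in 1:30) {
    fa <- f(theta)
    if (abs(fa) < 1e-13 * A0) break
    dfa <- (f(theta + 1e-9) - fa) / 1e-9
    step <- fa / dfa
    theta_new <- theta - step
    if (theta_new <= beta || theta_new >= pi / 2) break
    theta <- theta_new
  }
  R <- s_hat / (sin(theta) - sin(beta))
  out <- list(s_hat = s_hat, theta = theta, beta = beta, R = R,
              P = gamma / R, A0 = A0)
  class(out) <- "peel_shape"
  out
}

#' Reference enclosed area of the prepared vesicle
#'
#' Area enclosed between the adhesion mid-plane and the free contour at the
#' prepared state (a circle of radius \code{R0} cut by the chord of
#' half-length \code{s_hat0}); held constant during peeling.
#'
#' @param s_hat0 initial patch half-size, m.
#' @param R0 initial vesicle radius, m.
#' @return enclosed area, m^2.
#' @export
reference_area <- function(s_hat0, R0) {
  theta0 <- asin(s_hat0 / R0)
  vesicle_area(s_hat0, theta0, 0, R0)
}

#' @export
print.peel_shape <- function(x, ...) {
  cat(sprintf("<peel_shape> s_hat = %.4g um, theta = %.4g deg, beta = %.4g deg, R = %.4g um, P = %.4g Pa\n",
              x$s_hat * 1e6, x$theta * 180 / pi, x$beta * 180 / pi,
              x$R * 1e6, x$P))
  invisible(x)
}

#' Contour polyline of a solved vesicle shape
#'
#' Evaluates the free contour (right half plus mirrored left half) of a
#' \code{peel_shape} as an x,y polyline for plotting.
#'
#' @param shape a \code{peel_shape}.
#' @param n number of points per half.
#' @return data.frame with columns \code{x}, \code{y} in metres.
#' @export
shape_contour <- function(shape, n = 200) {
  psi <- seq(shape$theta, pi - shape$beta, length.out = n)
  x <- shape$s_hat + shape$R * (sin(psi) - sin(shape$theta))
  y <- shape$R * (cos(shape$theta) - cos(psi))
  data.frame(x = c(rev(-x), x), y = c(rev(y), y))
}

#' Peeling driving parameter
#'
#' \code{U = (1 - cos(theta)) / (1 - cos(theta0))}: the factor by which the
#' required interface bond concentration exceeds its prepared value. U = 1
#' at the prepared angle; U > 1 drives patch shrinkage.
#'
#' @param theta current contact angle, rad, in (0, pi).
#' @param theta0 prepared contact angle, rad, in (0, pi).
#' @return dimensionless driving parameter.
#' @export
driving_parameter <- function(theta, theta0) {
  stopifnot(all(theta > 0 & theta < pi), theta0 > 0, theta0 < pi)
  (1 - cos(theta)) / (1 - cos(theta0))
}
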