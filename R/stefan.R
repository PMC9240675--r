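# Closed-form similarity machinery for the diffusion-dominated regime.
#
# With reactions off, non-compliant bonds and constant contact angle, the
# bond field on the shrinking patch maps onto a classical one-phase Stefan
# problem. In the non-dimensional variables x = s/s_hat0 - 1, tau =
# t/tau_diff1, u = c1/C0 - U, the solution is self-similar in x/sqrt(tau).

stefan_residual <- function(lam, U) {
  sqrt(pi) * lam * exp(lam^2) * U * (erf(lam) + 1) - (1 - U)
}

#' Similarity constant lambda(U) of the Stefan peeling problem
#'
#' Solves the transcendental equation
#' \code{sqrt(pi) * lambda * exp(lambda^2) * U * (erf(lambda) + 1) = 1 - U}
#' for the similarity constant lambda. For U > 1 (force applied, interface
#' bond concentration raised above its prepared value) lambda < 0 and the
#' patch shrinks as \code{X(tau) = 2 * lambda * sqrt(tau)}; U = 1 gives
#' lambda = 0. Near U = 1, \code{lambda ~ -(U - 1)/sqrt(pi)}.
#'
#' @param U driving parameter \code{(1 - cos(theta)) / (1 - cos(theta0))},
#'   in (0, 50].
#' @return lambda, found by bracketed bisection with Newton polish to a
#'   residual below 1e-12.
#' @examples
#' lambda_of_U(1)     # 0
#' lambda_of_U(1.2)   # about -0.1055
#' @export
lambda_of_U <- function(U) {
  if (!is.numeric(U) || length(U) != 1L || is.na(U) || U <= 0 || U > 50) {
    stop("U must be a single number in (0, 50]", call. = FALSE)
  }
  if (U == 1) return(0)
  bracket <- if (U > 1) c(-5, 0) else c(0, 5)
  r <- stats::uniroot(stefan_residual, bracket, U = U, tol = 1e-14)
  lam <- r$root
  # Newton polish: d/dlam of sqrt(pi) lam e^(lam^2) U (erf(lam)+1)
  for (i in 1:20) {
    res <- stefan_residual(lam, U)
    if (abs(res) < 1e-13) break
    d <- sqrt(pi) * exp(lam^2) * U * ((1 + 2 * lam^2) * (erf(lam) + 1)) +
      2 * lam * U
    lam <- lam - res / d
  }
  lam
}

#' Self-similar bond-concentration profile
#'
#' Evaluates the similarity solution
#' \code{u(x, tau) = sqrt(pi) * lambda * exp(lambda^2) * U *
#' (erf(lambda) - erf(x / (2 sqrt(tau))))} of the diffusion-dominated
#' peeling problem. \code{u} is the rescaled bond concentration
#' \code{c1/C0 - U}; it vanishes at the interface \code{x = X(tau)} (where
#' c1 equals the Young-Dupre value U*C0) and tends to \code{1 - U} far
#' inside the patch (where c1 retains its prepared value C0).
#'
#' @param x non-dimensional position(s) \code{s/s_hat0 - 1}.
#' @param tau non-dimensional time \code{t/tau_diff1}, > 0.
#' @param U driving parameter.
#' @param lam optionally a precomputed \code{lambda_of_U(U)}.
#' @return u evaluated at \code{x} (vectorized).
#' @export
similarity_solution <- function(x, tau, U, lam = lambda_of_U(U)) {
  stopifnot(tau > 0)
  sqrt(pi) * lam * exp(lam^2) * U * (erf(lam) - erf(x / (2 * sqrt(tau))))
}

#' Rescaled interface position of the similarity solution
#'
#' \code{X(tau) = 2 * lambda * sqrt(tau)}, i.e. in physical units
#' \code{s_hat(t) = s_hat0 * (1 + 2 * lambda * sqrt(t / tau_diff1))}.
#'
#' @inheritParams similarity_solution
#' @return X(tau) (vectorized in \code{tau}).
#' @export
stefan_interface_position <- function(tau, U, lam = lambda_of_U(U)) {
  2 * lam * sqrt(tau)
}

#' Map between physical and similarity variables
#'
#' Bijective non-dimensionalization used by the Stefan comparison:
#' \code{x = s/s_hat0 - 1}, \code{tau = t/tau_diff1},
#' \code{u = c1/C0 - U}, \code{X = s_hat/s_hat0 - 1}. The inverse map is
#' returned alongside so round-trips are exact.
#'
#' @param s arc-length position(s), m (optional).
#' @param t time(s), s (optional).
#' @param c1 bond concentration(s), molecules/m^2 (optional).
#' @param s_hat interface position(s), m (optional).
#' @param s_hat0 initial patch half-size, m.
#' @param tau_diff1 patch diffusion time \code{s_hat0^2/D1}, s.
#' @param C0 interface concentration scale, molecules/m^2.
#' @param U driving parameter.
#' @return list with any of \code{x}, \code{tau}, \code{u}, \code{X}
#'   (for supplied inputs) plus an \code{inverse} function performing the
#'   reverse map on a like-named list.
#' @export
map_nondimensional <- function(s = NULL, t = NULL, c1 = NULL, s_hat = NULL,
                               s_hat0, tau_diff1, C0, U) {
  out <- list()
  if (!is.null(s)) out$x <- s / s_hat0 - 1
  if (!is.null(t)) out$tau <- t / tau_diff1
  if (!is.null(c1)) out$u <- c1 / C0 - U
  if (!is.null(s_hat)) out$X <- s_hat / s_hat0 - 1
  out$inverse <- function(nd) {
    inv <- list()
    if (!is.null(nd$x)) inv$s <- s_hat0 * (nd$x + 1)
    if (!is.null(nd$tau)) inv$t <- tau_diff1 * nd$tau
    if (!is.null(nd$u)) inv$c1 <- C0 * (nd$u + U)
    if (!is.null(nd$X)) inv$s_hat <- s_hat0 * (nd$X + 1)
    inv
  }
  out
}
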