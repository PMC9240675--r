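# Micro-mechanics of the adhesion patch: membrane separation profile h(x)
# on [0, alpha * s_hat] from minimization of the patch energy
#   E[h] = int gamma/2 h'^2 + kappa/2 h''^2 + (k c1/2) h^2 1[x<=s_hat]
#          + P h 1[x<=s_hat] dx - gamma sin(theta) h(alpha s_hat)
# (small-slope form; the exact sqrt(1+h'^2) capillary and curvature terms
# are available as a verification mode). Discretization: cubic Hermite
# (beam) finite elements, so the stationarity conditions reproduce the ODE
#   kappa h'''' - gamma h'' + k c1 h 1[x<=s_hat] = -P 1[x<=s_hat]
# with natural boundary conditions h''' = 0 at x = 0 (plus the essential
# symmetry condition h' = 0), and h'' = 0, kappa h''' - gamma h' =
# -gamma sin(theta) at the free end.

# 3-point Gauss rule on [-1, 1]
.gauss3 <- list(xi = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                w = c(5, 8, 5) / 9)

# Hermite shape functions and derivatives at reference coordinate xi for an
# element of length le (DOFs: h1, h1', h2, h2'; slopes w.r.t. x).
.hermite_N <- function(xi, le) {
  cbind((2 - 3 * xi + xi^3) / 4,
        le * (1 - xi - xi^2 + xi^3) / 8,
        (2 + 3 * xi - xi^3) / 4,
        le * (-1 - xi + xi^2 + xi^3) / 8)
}
.hermite_dN <- function(xi, le) {   # d/dx = (2/le) d/dxi
  cbind((-3 + 3 * xi^2) / 4,
        le * (-1 - 2 * xi + 3 * xi^2) / 8,
        (3 - 3 * xi^2) / 4,
        le * (-1 + 2 * xi + 3 * xi^2) / 8) * (2 / le)
}
.hermite_d2N <- function(xi, le) {  # d2/dx2 = (2/le)^2 d2/dxi2
  cbind(6 * xi / 4,
        le * (-2 + 6 * xi) / 8,
        -6 * xi / 4,
        le * (2 + 6 * xi) / 8) * (4 / le^2)
}

#' Graded micro-mechanics mesh
#'
#' Builds the node set on [0, alpha * s_hat] for the separation-profile
#' solver: fine uniform spacing (l2 / nfine nodes per boundary-layer
#' length) in a window of +/- \code{window} * l2 around the patch edge
#' x = s_hat, geometric coarsening away from it. A node is always placed
#' exactly at s_hat.
#'
#' @param s_hat patch half-size, m.
#' @param alpha domain factor (> 1).
#' @param l2 elastic-foundation boundary-layer length, m.
#' @param nfine nodes per l2 inside the refined window (default 10).
#' @param window half-width of the refined window in units of l2.
#' @param ratio geometric coarsening ratio outside the window.
#' @return numeric vector of node positions including 0 and alpha * s_hat.
#' @export
mm_mesh <- function(s_hat, alpha, l2, nfine = 10, window = 15,
                    ratio = 1.25) {
  stopifnot(s_hat > 0, alpha > 1, l2 > 0, l2 < s_hat)
  dx_fine <- l2 / nfine
  wL <- min(window * l2, 0.9 * s_hat)
  wR <- min(window * l2, (alpha - 1) * s_hat)
  # fine window [s_hat - wL, s_hat + wR]
  fine <- seq(s_hat - wL, s_hat + wR, by = dx_fine)
  if (fine[length(fine)] < s_hat + wR) fine <- c(fine, s_hat + wR)
  # coarse graded parts
  dx_max_in <- s_hat / 12
  left <- if (s_hat - wL > 0) {
    (s_hat - wL) - rev(graded_offsets(s_hat - wL, dx_fine, dx_max_in, ratio))
  } else numeric(0)
  right_len <- alpha * s_hat - (s_hat + wR)
  right <- if (right_len > 1e-12 * s_hat) {
    (s_hat + wR) + graded_offsets(right_len, dx_fine, dx_max_in, ratio)
  } else numeric(0)
  x <- sort(unique(c(0, left, fine, right, s_hat, alpha * s_hat)))
  # drop near-duplicates
  keep <- c(TRUE, diff(x) > 1e-6 * dx_fine)
  x[keep]
}

# Assemble and solve the small-slope Hermite system. c1_at: function(x)
# giving the bond concentration (only evaluated on [0, s_hat]).
.solve_beam_linear <- function(x, s_hat, c1_at, gamma, kappa, k, P,
                               end_shear) {
  M <- length(x) - 1L
  le <- diff(x)
  ndof <- 2L * (M + 1L)
  g3 <- .gauss3
  # triplet accumulators
  ii <- jj <- vv <- vector("list", 0L)
  dof1 <- 2L * seq_len(M) - 1L          # h at left node of element
  dofmap <- cbind(dof1, dof1 + 1L, dof1 + 2L, dof1 + 3L)
  rhs <- numeric(ndof)
  Kab <- matrix(0, M, 16L)              # accumulated element entries
  # bending + tension closed-form patterns
  pat_b <- function(le) {
    cbind(12, 6 * le, -12, 6 * le,
          6 * le, 4 * le^2, -6 * le, 2 * le^2,
          -12, -6 * le, 12, -6 * le,
          6 * le, 2 * le^2, -6 * le, 4 * le^2) / le^3
  }
  pat_g <- function(le) {
    cbind(36, 3 * le, -36, 3 * le,
          3 * le, 4 * le^2, -3 * le, -le^2,
          -36, -3 * le, 36, -3 * le,
          3 * le, -le^2, -3 * le, 4 * le^2) / (30 * le)
  }
  Kab <- kappa * pat_b(le) + gamma * pat_g(le)
  # foundation and pressure via Gauss quadrature, restricted to the patch
  for (g in seq_along(g3$xi)) {
    xi <- g3$xi[g]
    w <- g3$w[g]
    xg <- x[-length(x)] + (xi + 1) / 2 * le
    on_patch <- xg <= s_hat + 1e-9 * s_hat
    q <- ifelse(on_patch, k * c1_at(pmin(xg, s_hat)), 0)
    N <- .hermite_N(xi, le)             # M x 4
    scale <- w * le / 2
    # outer products N_a N_b accumulated entry-wise
    idx <- 0L
    for (a in 1:4) for (b in 1:4) {
      idx <- idx + 1L
      Kab[, idx] <- Kab[, idx] + scale * q * N[, a] * N[, b]
    }
    # pressure load (energy + int P h => force -P)
    Pg <- ifelse(on_patch, P, 0)
    for (a in 1:4) {
      rhs_add <- -scale * Pg * N[, a]
      rhs_idx <- dofmap[, a]
      rhs[rhs_idx] <- rhs[rhs_idx] + rhs_add
    }
  }
  rows <- as.vector(dofmap[, rep(1:4, each = 4)])
  cols <- as.vector(dofmap[, rep(1:4, times = 4)])
  vals <- as.vector(Kab)
  # essential BC h'(0) = 0 (DOF 2) applied in triplet space: dropping the
  # row/column and pinning the diagonal avoids costly sparse subassignment
  keep <- rows != 2L & cols != 2L
  K <- Matrix::sparseMatrix(i = c(rows[keep], 2L), j = c(cols[keep], 2L),
                            x = c(vals[keep], 1), dims = c(ndof, ndof))
  # boundary work term: + end_shear at h(L)
  rhs[ndof - 1L] <- rhs[ndof - 1L] + end_shear
  rhs[2L] <- 0
  # symmetric Jacobi scaling: displacement and slope DOFs differ by many
  # orders of magnitude in stiffness, which defeats the sparse solver's
  # conditioning check on nanometric meshes
  d <- 1 / sqrt(Matrix::diag(K))
  Dm <- Matrix::Diagonal(x = d)
  sol <- d * as.numeric(Matrix::solve(Dm %*% K %*% Dm, d * rhs))
  h <- sol[seq(1L, ndof, by = 2L)]
  dh <- sol[seq(2L, ndof, by = 2L)]
  list(h = h, dh = dh, dof = sol)
}

# discrete traction integral int k c1 h dx with the assembly quadrature
.traction_integral <- function(x, dof, s_hat, c1_at, k) {
  M <- length(x) - 1L
  le <- diff(x)
  g3 <- .gauss3
  dof1 <- 2L * seq_len(M) - 1L
  total <- 0
  for (g in seq_along(g3$xi)) {
    xi <- g3$xi[g]
    w <- g3$w[g]
    xg <- x[-length(x)] + (xi + 1) / 2 * le
    on_patch <- xg <= s_hat + 1e-9 * s_hat
    q <- ifelse(on_patch, k * c1_at(pmin(xg, s_hat)), 0)
    N <- .hermite_N(xi, le)
    hg <- N[, 1] * dof[dof1] + N[, 2] * dof[dof1 + 1L] +
      N[, 3] * dof[dof1 + 2L] + N[, 4] * dof[dof1 + 3L]
    total <- total + sum(w * le / 2 * q * hg)
  }
  total
}

#' Membrane separation profile over the adhesion patch
#'
#' Minimizes the micro-mechanical energy of the patch and its margin,
#' returning the separation h(x) relative to the unstressed bond length
#' (h > 0 = stretched bond) and the per-bond force k*h. The membrane is
#' loaded at the far end x = alpha*s_hat by the transverse component
#' gamma*sin(theta) of the free-membrane tension; the vesicle pressure P
#' presses it onto the bonds (h < 0 side) over the patch.
#'
#' @param c1 bond concentration over the patch: either a function of
#'   position (m -> molecules/m^2) or a vector on an equispaced grid over
#'   [0, s_hat] (interpolated internally).
#' @param gamma membrane tension, N/m.
#' @param theta contact angle, rad.
#' @param P Laplace pressure, N/m^2 (per unit depth).
#' @param params a \code{\link{peel_params}} object (uses kappa, k, alpha).
#' @param s_hat patch half-size, m (default \code{params$s_hat0}).
#' @param mesh optional precomputed node vector from \code{\link{mm_mesh}}.
#' @param nonlinear logical; verify with the full non-linear energy (exact
#'   arc-length and curvature terms) minimized by BFGS from the
#'   small-slope solution.
#' @return object of class \code{peel_profile}: \code{x}, \code{h},
#'   \code{dh}, \code{per_bond_force} (k*h), \code{traction} (k*c1*h on the
#'   patch, 0 outside), \code{traction_integral} (discrete
#'   \code{int k c1 h dx}), \code{s_hat}.
#' @export
solve_separation <- function(c1, gamma, theta, P, params,
                             s_hat = params$s_hat0, mesh = NULL,
                             nonlinear = FALSE) {
  validate_peel_params(params)
  check_positive(s_hat, "s_hat")
  c1_at <- if (is.function(c1)) {
    c1
  } else {
    stopifnot(all(c1 >= 0))
    xs <- seq(0, s_hat, length.out = length(c1))
    stats::approxfun(xs, c1, rule = 2)
  }
  c1_edge <- c1_at(s_hat)
  if (c1_edge <= 0 && gamma <= 0) {
    stop("singular stiffness: c1 = 0 with gamma = 0", call. = FALSE)
  }
  if (is.null(mesh)) {
    c1_typ <- max(c1_edge, c1_at(0.5 * s_hat), params$c0)
    l2 <- (4 * params$kappa / (params$k * c1_typ))^(1 / 4)
    mesh <- mm_mesh(s_hat, params$alpha, l2)
  }
  sol <- .solve_beam_linear(mesh, s_hat, c1_at, gamma, params$kappa,
                            params$k, P, end_shear = gamma * sin(theta))
  if (nonlinear) {
    sol <- .polish_nonlinear(mesh, sol, s_hat, c1_at, gamma, params$kappa,
                             params$k, P, gamma * sin(theta))
  }
  on_patch <- mesh <= s_hat + 1e-9 * s_hat
  out <- list(
    x = mesh, h = sol$h, dh = sol$dh,
    per_bond_force = params$k * sol$h,
    traction = ifelse(on_patch, params$k * c1_at(pmin(mesh, s_hat)) * sol$h, 0),
    traction_integral = .traction_integral(mesh, sol$dof, s_hat, c1_at,
                                           params$k),
    s_hat = s_hat, theta = theta, P = P, gamma = gamma)
  class(out) <- "peel_profile"
  out
}

# full nonlinear energy: gamma*sqrt(1+h'^2) + kappa/2 h''^2/(1+h'^2)^(5/2)
# + foundation + pressure - end work; minimized by L-BFGS with analytic
# gradient, warm-started from the small-slope solution.
.polish_nonlinear <- function(x, sol0, s_hat, c1_at, gamma, kappa, k, P,
                              end_shear) {
  M <- length(x) - 1L
  le <- diff(x)
  ndof <- 2L * (M + 1L)
  g3 <- .gauss3
  dof1 <- 2L * seq_len(M) - 1L
  dofmap <- cbind(dof1, dof1 + 1L, dof1 + 2L, dof1 + 3L)
  # precompute shape tables per Gauss point
  tabs <- lapply(seq_along(g3$xi), function(g) {
    xi <- g3$xi[g]
    xg <- x[-length(x)] + (xi + 1) / 2 * le
    on_patch <- xg <= s_hat + 1e-9 * s_hat
    list(N = .hermite_N(xi, le), dN = .hermite_dN(xi, le),
         d2N = .hermite_d2N(xi, le), w = g3$w[g] * le / 2,
         q = ifelse(on_patch, k * c1_at(pmin(xg, s_hat)), 0),
         Pg = ifelse(on_patch, P, 0))
  })
  eval_fields <- function(u, tab) {
    list(h = tab$N[, 1] * u[dofmap[, 1]] + tab$N[, 2] * u[dofmap[, 2]] +
           tab$N[, 3] * u[dofmap[, 3]] + tab$N[, 4] * u[dofmap[, 4]],
         hp = tab$dN[, 1] * u[dofmap[, 1]] + tab$dN[, 2] * u[dofmap[, 2]] +
           tab$dN[, 3] * u[dofmap[, 3]] + tab$dN[, 4] * u[dofmap[, 4]],
         hpp = tab$d2N[, 1] * u[dofmap[, 1]] + tab$d2N[, 2] * u[dofmap[, 2]] +
           tab$d2N[, 3] * u[dofmap[, 3]] + tab$d2N[, 4] * u[dofmap[, 4]])
  }
  energy <- function(u) {
    E <- -end_shear * u[ndof - 1L]
    for (tab in tabs) {
      f <- eval_fields(u, tab)
      m <- 1 + f$hp^2
      E <- E + sum(tab$w * (gamma * sqrt(m) + kappa / 2 * f$hpp^2 / m^(5 / 2) +
                            tab$q / 2 * f$h^2 + tab$Pg * f$h))
    }
    E
  }
  grad <- function(u) {
    gvec <- numeric(ndof)
    gvec[ndof - 1L] <- -end_shear
    for (tab in tabs) {
      f <- eval_fields(u, tab)
      m <- 1 + f$hp^2
      dE_dh <- tab$q * f$h + tab$Pg
      dE_dhp <- gamma * f$hp / sqrt(m) -
        5 * kappa / 2 * f$hpp^2 * f$hp / m^(7 / 2)
      dE_dhpp <- kappa * f$hpp / m^(5 / 2)
      for (a in 1:4) {
        contr <- tab$w * (dE_dh * tab$N[, a] + dE_dhp * tab$dN[, a] +
                          dE_dhpp * tab$d2N[, a])
        idx <- dofmap[, a]
        gvec[idx] <- gvec[idx] + contr
      }
    }
    gvec[2L] <- 0   # essential BC h'(0) = 0
    gvec
  }
  u0 <- sol0$dof
  u0[2L] <- 0
  fit <- stats::optim(u0, energy, grad, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  if (fit$convergence != 0) {
    stop("nonlinear separation solve did not converge: ", fit$message,
         call. = FALSE)
  }
  u <- fit$par
  list(h = u[seq(1L, ndof, by = 2L)], dh = u[seq(2L, ndof, by = 2L)],
       dof = u)
}

#' Peak per-bond force over the patch
#'
#' Maximum over the patch of the per-molecule force magnitude k*|h|; the
#' relevant comparison scale for slip-bond sensitivity is f_gamma =
#' sqrt(k*kBT).
#'
#' @param profile a \code{peel_profile} from \code{\link{solve_separation}}.
#' @param params a \code{\link{peel_params}} object.
#' @return force, N.
#' @export
per_bond_force_scale <- function(profile, params) {
  on_patch <- profile$x <= profile$s_hat + 1e-9 * profile$s_hat
  max(abs(params$k * profile$h[on_patch]))
}

#' @export
print.peel_profile <- function(x, ...) {
  cat(sprintf(
    "<peel_profile> %d nodes on [0, %.3g um]; max|h| = %.3g nm; max per-bond force = %.3g pN\n",
    length(x$x), max(x$x) * 1e6, max(abs(x$h)) * 1e9,
    max(abs(x$per_bond_force)) * 1e12))
  invisible(x)
}
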