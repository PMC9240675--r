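# Reaction-diffusion of bonds and free binders on the moving adhesion patch,
# coupled quasi-statically to vesicle capillarity and patch micro-mechanics.
#
# Discretization. Front-fixing: the patch [0, s_hat(t)] maps to a fixed
# reference grid xi in [0,1], the outer membrane [s_hat, L0] to eta in
# [0,1]; both are cell-centered finite-volume grids whose faces move with
# the mapping (ALE). Fluxes through moving faces use the total flux
# T = w*c - J (w = face velocity, J = diffusive + drift flux), implicit in
# the concentrations with upwinded advection, so the scheme is an M-matrix
# (positivity) and telescopes exactly (conservation to machine precision:
# the interface face is a zero-total-flux face for bonds, which is
# precisely the bond interface condition). The interface velocity v_hat is
# the scalar unknown that makes the reconstructed bond concentration at the
# interface face equal the Young-Dupre value; it is found by a secant
# iteration wrapped around the implicit transport solve. Reactions are
# advanced by a preceding backward-Euler substep solved per cell, which
# conserves c1 + c2 cell-wise exactly.

# ---- grids -----------------------------------------------------------------

# cell-centered graded reference grid on [0,1], refined toward 1:
# face spacing dmin at 1 growing geometrically to dmax toward 0
.ref_grid <- function(dmin, dmax, ratio = 1.35) {
  offs <- graded_offsets(1, dmin, dmax, ratio)
  faces <- rev(1 - c(0, offs))
  list(faces = faces, centers = (faces[-1] + faces[-length(faces)]) / 2,
       dxi = diff(faces))
}

#' Build the solver grid
#'
#' Reference grids for the bond field (patch, refined toward the interface)
#' and the free-binder field (patch grid plus an outer grid on
#' [s_hat, L0] refined toward the interface from the right). Refinement is
#' set by the physical process-zone scales at the initial patch size:
#' minimum spacing \code{min(l2/10, l3/4)} near the interface (bounded
#' below for practicality), coarse spacing a fraction of the domain
#' elsewhere.
#'
#' @param params a \code{\link{peel_params}} object.
#' @param gamma membrane tension used for the scale estimates, N/m.
#' @param c1ref reference bond concentration for l2, molecules/m^2.
#' @param resolution multiplier on the near-interface spacing (1 = default;
#'   larger = coarser).
#' @return list of reference-grid descriptions used by
#'   \code{\link{run_peeling}}.
#' @export
rd_grid <- function(params, gamma, c1ref, resolution = 1) {
  s0 <- params$s_hat0
  scl <- derive_scales(params, c1ref = c1ref, gamma = gamma)
  dx_layers <- c(if (params$compliant) scl$l2 / 10 else Inf,
                 if (params$koff_bar > 0) scl$l3 / 4 else Inf,
                 s0 / 500)
  dx_min <- min(dx_layers) * resolution
  dx_min <- max(dx_min, 2e-10)          # practical floor, 0.2 nm
  patch <- .ref_grid(dx_min / s0, 1 / 16)
  Louter <- params$L0 - s0
  outer_dmin <- max(dx_min, scl$l3, na.rm = TRUE) / Louter
  outer <- .ref_grid(min(outer_dmin, 0.02), 1 / 12)
  # outer grid refined toward eta = 0 (the interface): mirror it
  of <- rev(1 - outer$faces)
  outer <- list(faces = of, centers = (of[-1] + of[-length(of)]) / 2,
                dxi = diff(of))
  list(patch = patch, outer = outer,
       N = length(patch$centers), M = length(outer$centers))
}

# ---- small linear algebra --------------------------------------------------

# Thomas algorithm for a tridiagonal system (diag d, upper u, lower l)
.thomas <- function(l, d, u, b) {
  n <- length(d)
  cp <- numeric(n); bp <- numeric(n)
  cp[1] <- u[1] / d[1]
  bp[1] <- b[1] / d[1]
  for (i in 2:n) {
    m <- d[i] - l[i] * cp[i - 1]
    cp[i] <- if (i < n) u[i] / m else 0
    bp[i] <- (b[i] - l[i] * bp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  x
}

# Implicit conservative ALE transport step for one species.
#   Vnew, Vold : cell volumes (lengths), length N
#   cold       : concentrations at step start
#   Dface, vel : diffusivity and net advective coefficient per interior
#                face (length N-1); face f sits between cells f and f+1
#   delta      : center-to-center distances at the new geometry (N-1)
# Boundary faces carry zero total flux. Returns c_new.
.transport <- function(cold, Vold, Vnew, Dface, vel, delta, dt) {
  n <- length(cold)
  a <- Dface / delta
  # hybrid face value for the advected concentration: central where the
  # cell Peclet number allows (second order, no numerical diffusion),
  # upwind otherwise; both keep the update an M-matrix
  central <- abs(vel) < 2 * a
  q <- ifelse(central, a + vel / 2, a + pmax(vel, 0))
  p <- ifelse(central, -a + vel / 2, -a + pmin(vel, 0))
  diag <- Vnew
  upper <- numeric(n); lower <- numeric(n)
  diag[-n] <- diag[-n] - dt * p
  upper[-n] <- -dt * q
  diag[-1] <- diag[-1] + dt * q
  lower[-1] <- dt * p
  .thomas(lower, diag, upper, Vold * cold)
}

# quadratic extrapolation of cell-center values to a boundary face
.extrap_face <- function(xc, c, xface) {
  n <- length(xc)
  if (n < 3) return(c[n])
  x <- xc[(n - 2):n] - xface
  y <- c[(n - 2):n]
  # Lagrange evaluation at 0
  L <- function(j) {
    others <- setdiff(1:3, j)
    prod(-x[others]) / prod(x[j] - x[others])
  }
  y[1] * L(1) + y[2] * L(2) + y[3] * L(3)
}

#' Interface velocity from the bond interface condition
#'
#' Evaluates \code{v_hat = -D1 * (c1' + c1 * ((h/x_gamma)^2)') / c1(s_hat)}
#' at the patch edge with second-order one-sided differences on the patch
#' side: the diffusive (and stretch-biased) bond flux arriving at the
#' interface must be carried by interface motion, since the interface is a
#' barrier for bonds.
#'
#' @param s positions on the patch, m (increasing, last = s_hat).
#' @param c1 bond concentrations at \code{s}.
#' @param h separations at \code{s} (0 for non-compliant bonds).
#' @param params a \code{\link{peel_params}} object.
#' @return v_hat, m/s (negative = shrinking patch).
#' @export
interface_velocity <- function(s, c1, h, params) {
  n <- length(s)
  stopifnot(length(c1) == n, n >= 3)
  cg <- c1[n]
  if (cg <= 0) stop("interface bond concentration is zero", call. = FALSE)
  xg <- sqrt(params$kBT / params$k)
  Phi <- (h / xg)^2
  dc <- onesided_deriv_last(s, c1)
  dPhi <- onesided_deriv_last(s, Phi)
  -params$D1 * (dc + cg * dPhi) / cg
}

# ---- reactions -------------------------------------------------------------

# Backward-Euler reaction substep on patch cells. Conserves c1 + c2 per
# cell exactly. kon, koff vectors per cell. Vectorized clamped Newton.
.react_be <- function(c1, c2, kon, koff, dt) {
  S <- c1 + c2
  x <- c1
  for (it in 1:60) {
    Fx <- x - c1 - dt * (kon * (S - x)^2 - koff * x)
    dF <- 1 + dt * (2 * kon * (S - x) + koff)
    step <- Fx / dF
    x_new <- pmin(pmax(x - step, 0), S)
    if (max(abs(x_new - x) / pmax(S, 1e-300)) < 1e-14) {
      x <- x_new
      break
    }
    x <- x_new
  }
  list(c1 = x, c2 = S - x)
}

# ---- simulation container --------------------------------------------------

.new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$cap <- 1024L
  for (f in c("t", "s_hat", "theta", "v_hat", "N1", "N2", "dt")) {
    assign(f, numeric(1024L), envir = env)
  }
  env$snaps <- list()
  env
}

.record_scalar <- function(rec, vals) {
  if (rec$n == rec$cap) {
    rec$cap <- rec$cap * 2L
    for (f in c("t", "s_hat", "theta", "v_hat", "N1", "N2", "dt")) {
      v <- get(f, envir = rec)
      length(v) <- rec$cap
      assign(f, v, envir = rec)
    }
  }
  rec$n <- rec$n + 1L
  i <- rec$n
  for (f in names(vals)) {
    v <- get(f, envir = rec)
    v[i] <- vals[[f]]
    assign(f, v, envir = rec)
  }
}

# ---- main driver -----------------------------------------------------------

#' Run a peeling simulation
#'
#' Prepares the equilibrium state, applies the force at t = 0 and
#' integrates the coupled mechano-chemical dynamics until \code{t_end},
#' complete failure (patch half-size below \code{s_min}), or abort.
#'
#' Each accepted step performs: (1) quasi-static vesicle shape solve for
#' the contact angle (or holds it fixed in constant-theta mode);
#' (2) micro-mechanical separation profile (compliant mode; otherwise
#' h = 0); (3) interface bond concentration from the Young-Dupre balance;
#' (4) backward-Euler reaction substep (cell-wise conservative);
#' (5) implicit conservative ALE transport of bonds and free binders with
#' the interface velocity determined so the reconstructed interface bond
#' concentration matches the Young-Dupre value. Time steps adapt to the
#' interface CFL condition and to the relative change of the fields;
#' negative concentrations or failed interface iterations reject the step
#' and halve dt.
#'
#' @param params a \code{\link{peel_params}} object.
#' @param t_end end time, s.
#' @param theta_fixed contact angle, rad, for constant-theta mode. If
#'   \code{NULL} and \code{params$constant_theta}, the angle solved at t=0
#'   (after force application) is held.
#' @param s_min failure threshold on the patch half-size, m; default
#'   \code{max(5*l2, 0.01*s_hat0)}.
#' @param resolution grid-resolution multiplier (see \code{\link{rd_grid}}).
#' @param snap_times times at which to store full field snapshots
#'   (concentrations, potentials, separations, net reaction rate).
#' @param prerelax logical; relax the compliant state at F = 0 before
#'   applying the force (the uniform prepared state is not an equilibrium
#'   for compliant bonds). Default: compliant mode with capillary coupling.
#' @param prerelax_time cap on the relaxation time, s.
#' @param dt0 initial time step, s (default from the near-interface cell
#'   diffusion time).
#' @param max_steps hard cap on accepted steps.
#' @param step_tol target relative field change per step (adaptivity).
#' @param verbose logical; print progress.
#' @return object of class \code{peel_trajectory}: scalar series
#'   (\code{t}, \code{s_hat}, \code{theta}, \code{v_hat}, \code{N1},
#'   \code{N2}, \code{dt}), snapshots, \code{t_fail} (Inf if no failure),
#'   \code{status}, the equilibrium state, scales and grid.
#' @export
run_peeling <- function(params, t_end,
                        theta_fixed = NULL,
                        s_min = NULL,
                        resolution = 1,
                        snap_times = numeric(0),
                        prerelax = params$compliant && !params$constant_theta,
                        prerelax_time = NULL,
                        dt0 = NULL,
                        max_steps = 2e5,
                        step_tol = 0.02,
                        verbose = FALSE) {
  validate_peel_params(params)
  eq <- prepare_equilibrium(params)
  gamma <- params$gamma %||% eq$gamma_eq
  Fap <- params$F_over_gamma * gamma
  scl <- derive_scales(params, c1ref = eq$c1_eq, gamma = gamma)
  grid <- rd_grid(params, gamma, eq$c1_eq, resolution = resolution)
  A0 <- reference_area(params$s_hat0, params$R0)
  if (is.null(s_min)) {
    s_min <- max(5 * scl$l2, 0.01 * params$s_hat0)
  }

  sim <- list(params = params, eq = eq, gamma = gamma, F = Fap,
              scl = scl, grid = grid, A0 = A0, s_min = s_min)

  # micro-mechanics reference mesh on [0, alpha] (xi = x / s_hat)
  if (params$compliant) {
    sim$mm_ref <- mm_mesh(1, params$alpha, scl$l2 / params$s_hat0,
                          nfine = max(6, 10 / sqrt(resolution)))
  }

  # initial state: uniform prepared concentrations
  state <- list(t = 0,
                s_hat = params$s_hat0,
                c1 = rep(eq$c1_eq, grid$N),
                c2 = rep(eq$c2_eq, grid$N + grid$M),
                v_hat = 0, theta = eq$theta0)

  if (prerelax) {
    sim_relax <- sim
    sim_relax$F <- 0
    state <- .integrate(sim_relax, state,
                        t_end = prerelax_time %||% (2 * scl$tau_diff1),
                        theta_fixed = NULL, dt0 = dt0, max_steps = max_steps,
                        step_tol = step_tol, snap_times = numeric(0),
                        rec = NULL, relax_mode = TRUE, verbose = verbose)$state
    state$t <- 0
  }

  rec <- .new_recorder()
  res <- .integrate(sim, state, t_end = t_end, theta_fixed = theta_fixed,
                    dt0 = dt0, max_steps = max_steps, step_tol = step_tol,
                    snap_times = snap_times, rec = rec, relax_mode = FALSE,
                    verbose = verbose)
  n <- rec$n
  traj <- list(
    t = rec$t[1:n], s_hat = rec$s_hat[1:n], theta = rec$theta[1:n],
    v_hat = rec$v_hat[1:n], N1 = rec$N1[1:n], N2 = rec$N2[1:n],
    dt = rec$dt[1:n],
    snapshots = rec$snaps,
    t_fail = res$t_fail, status = res$status,
    equilibrium = eq, scales = scl, grid = grid, params = params,
    gamma = gamma, s_min = s_min, state = res$state)
  class(traj) <- "peel_trajectory"
  traj
}

# one full integration loop; returns list(state, t_fail, status)
.integrate <- function(sim, state, t_end, theta_fixed, dt0, max_steps,
                       step_tol, snap_times, rec, relax_mode, verbose) {
  p <- sim$params
  grid <- sim$grid
  snap_times <- sort(snap_times)
  next_snap <- if (length(snap_times)) 1L else 0L
  t_fail <- Inf
  status <- "t_end"
  # constant-theta mode: solve the shape once at t = 0 unless given
  if (p$constant_theta && is.null(theta_fixed) && !relax_mode) {
    sh0 <- solve_vesicle_shape(sim$gamma, sim$F, state$s_hat, sim$A0)
    theta_fixed <- sh0$theta
  }
  dxmin_ref <- min(grid$patch$dxi)
  sim$dxmin_ref <- dxmin_ref
  dt <- dt0 %||% (0.5 * (dxmin_ref * state$s_hat)^2 / p$D1)
  rejections <- 0L
  step <- 0L
  while (step < max_steps && state$t < t_end) {
    dt <- min(dt, t_end - state$t)
    # snapshot alignment: do not step across a requested snapshot time
    if (next_snap > 0L && next_snap <= length(snap_times)) {
      gap <- snap_times[next_snap] - state$t
      if (gap > 1e-300 && dt > gap) dt <- gap
    }
    trial <- .advance_step(sim, state, dt, theta_fixed, relax_mode)
    if (!trial$ok) {
      rejections <- rejections + 1L
      if (rejections > 20L) {
        status <- paste0("abort: ", trial$why)
        break
      }
      dt <- dt / 2
      next
    }
    rejections <- 0L
    state <- trial$state
    step <- step + 1L
    if (!is.null(rec)) {
      .record_scalar(rec, list(
        t = state$t, s_hat = state$s_hat, theta = state$theta,
        v_hat = state$v_hat, N1 = state$N1, N2 = state$N2, dt = dt))
    }
    if (next_snap > 0L && next_snap <= length(snap_times) &&
        state$t >= snap_times[next_snap] - 1e-12 * max(snap_times)) {
      if (!is.null(rec)) {
        rec$snaps[[length(rec$snaps) + 1L]] <- .make_snapshot(sim, state)
      }
      next_snap <- next_snap + 1L
    }
    if (verbose && step %% 500L == 0L) {
      message(sprintf("  t = %.4g s  s_hat = %.4g um  dt = %.3g s",
                      state$t, state$s_hat * 1e6, dt))
    }
    if (state$s_hat <= sim$s_min) {
      t_fail <- state$t
      status <- "failure"
      break
    }
    if (relax_mode && abs(state$v_hat) * sim$scl$tau_diff1 <
        1e-6 * p$s_hat0 && state$t > 10 * dt) {
      status <- "relaxed"
      break
    }
    # adapt dt
    dt <- dt * min(1.4, max(0.3, 0.9 * step_tol / max(trial$err, 1e-12)))
    dxmin_phys <- dxmin_ref * state$s_hat
    if (abs(state$v_hat) > 0) {
      dt <- min(dt, 0.2 * dxmin_phys / abs(state$v_hat))
    }
  }
  if (step >= max_steps) status <- "max_steps"
  list(state = state, t_fail = t_fail, status = status)
}

# single trial step; returns list(ok, state | why, err)
.advance_step <- function(sim, state, dt, theta_fixed, relax_mode) {
  p <- sim$params
  g <- sim$grid
  s_old <- state$s_hat
  # (1) vesicle shape / contact angle
  if (!is.null(theta_fixed) && p$constant_theta && !relax_mode) {
    theta <- theta_fixed
    beta <- asin(sim$F / (2 * sim$gamma))
    R <- s_old / max(sin(theta) - sin(beta), 1e-12)
    P <- sim$gamma / R
  } else {
    sh <- tryCatch(
      solve_vesicle_shape(sim$gamma, if (relax_mode) 0 else sim$F,
                          s_old, sim$A0),
      error = function(e) NULL)
    if (is.null(sh)) return(list(ok = FALSE, why = "shape solve failed"))
    theta <- sh$theta
    P <- sh$P
  }
  # (2) separation profile
  xc_patch <- g$patch$centers * s_old
  if (p$compliant) {
    c1_at <- stats::approxfun(
      c(0, xc_patch, s_old),
      c(state$c1[1], state$c1, .extrap_face(xc_patch, state$c1, s_old)),
      rule = 2)
    prof <- tryCatch(
      solve_separation(c1_at, sim$gamma, theta, P, p, s_hat = s_old,
                       mesh = sim$mm_ref * s_old),
      error = function(e) NULL)
    if (is.null(prof)) return(list(ok = FALSE, why = "separation solve failed"))
    h_centers <- stats::approx(prof$x, prof$h, xout = xc_patch, rule = 2)$y
    h_face <- stats::approx(prof$x, prof$h, xout = s_old, rule = 2)$y
  } else {
    prof <- NULL
    h_centers <- numeric(g$N)
    h_face <- 0
  }
  xg <- sqrt(p$kBT / p$k)
  Phi_c <- (h_centers / xg)^2
  Phi_face <- (h_face / xg)^2
  # (3) interface bond concentration (Young-Dupre)
  c1_gamma <- interface_concentration(list(theta = theta), sim$gamma, p)
  # (4) reactions (patch cells only)
  c1 <- state$c1
  c2 <- state$c2
  if (p$reactions_on && p$koff_bar > 0) {
    rates <- rate_functions(h_centers, p)
    rs <- .react_be(c1, c2[1:g$N], rates$kon, rates$koff, dt)
    c1 <- rs$c1
    c2[1:g$N] <- rs$c2
  }
  # (5) transport with interface-velocity iteration
  sol <- .transport_coupled(sim, c1, c2, s_old, state$v_hat, dt, Phi_c,
                            c1_gamma, Phi_face)
  if (!sol$ok) return(list(ok = FALSE, why = sol$why))
  # a-posteriori guard against gross interface motion in one step (the
  # startup velocity diverges like 1/sqrt(t); sub-cell startup motion is
  # legitimate, several cells per step is not)
  dxmin_phys <- sim$dxmin_ref * s_old
  if (abs(sol$v_hat) * dt > 2 * dxmin_phys && state$t > 0) {
    return(list(ok = FALSE, why = "interface CFL"))
  }
  if (min(sol$c1) < -1e-12 * c1_gamma || min(sol$c2) < 0) {
    return(list(ok = FALSE, why = "negative concentration"))
  }
  s_new <- s_old + sol$v_hat * dt
  if (s_new <= 0) return(list(ok = FALSE, why = "interface crossed origin"))
  if (p$crowding &&
      max(sol$c1 + sol$c2[1:g$N]) >= p$cmax * (1 - 1e-12)) {
    return(list(ok = FALSE, why = "crowding overflow"))
  }
  # bookkeeping
  V1 <- g$patch$dxi * s_new
  V2 <- c(V1, g$outer$dxi * (p$L0 - s_new))
  N1 <- sum(sol$c1 * V1)
  N2 <- sum(sol$c2 * V2)
  # step-size control on mass-weighted mean changes: single stiff cells at
  # the patch edge equilibrate within one substep at any dt and must not
  # drive dt to zero (interface motion is CFL-capped separately)
  err <- max(sum(abs(sol$c1 - state$c1) * V1) / sum(pmax(state$c1, 0) * V1),
             sum(abs(sol$c2 - state$c2) * V2) / sum(pmax(state$c2, 0) * V2),
             abs(s_new - s_old) / s_old)
  new_state <- list(t = state$t + dt, s_hat = s_new, c1 = sol$c1,
                    c2 = sol$c2, v_hat = sol$v_hat, theta = theta,
                    N1 = N1, N2 = N2, h = h_centers, P = P,
                    c1_gamma = c1_gamma, profile = prof)
  list(ok = TRUE, state = new_state, err = err)
}

# transport of both species for a trial dt. The interface velocity is the
# discrete bond interface law evaluated through the Young-Dupre face value
# (ghost value): v_hat = -D1 (c1' + c_bar Phi') / c1_gamma with a
# second-order one-sided derivative over the last two cell centres and the
# face. The interface face itself carries zero total flux (no bond crosses
# a moving barrier), so bond number is conserved exactly; the Dirichlet
# value steers the dynamics through v_hat, a self-correcting feedback
# (interior value below c1_gamma -> steeper ghost gradient -> faster
# inward motion -> compression raises the interior value).
.transport_coupled <- function(sim, c1, c2, s_old, v_prev, dt, Phi_c,
                               c1_gamma, Phi_face = 0) {
  p <- sim$params
  g <- sim$grid
  N <- g$N
  xi_c <- g$patch$centers
  xi_f <- g$patch$faces
  crowd <- p$crowding
  c2p <- c2[1:N]
  if (crowd) {
    vacc <- p$cmax - c1 - c2p
    vac_f <- (vacc[-1] + vacc[-N]) / 2
    c1_f <- (c1[-1] + c1[-N]) / 2
    c2_face <- .extrap_face(xi_c * s_old, c2p, s_old)
    vacc_face <- p$cmax - c1_gamma - c2_face
    if (vacc_face <= 0) {
      return(list(ok = FALSE, why = "crowding overflow at interface"))
    }
  }
  solve_c1 <- function(v_hat) {
    s_new <- s_old + v_hat * dt
    if (s_new <= 0) return(NULL)
    delta <- diff(xi_c) * s_new
    Vold <- g$patch$dxi * s_old
    Vnew <- g$patch$dxi * s_new
    Dface <- rep(p$D1, N - 1)
    vel <- xi_f[2:N] * v_hat + p$D1 * diff(Phi_c) / delta
    if (crowd) {
      # crowded flux J1 = -D1 [c1' + 2 c1 (c1' + c2')/vacc + c1 Phi']:
      # the c1' part enhances the diffusivity, the c2' part advects c1
      Dface <- p$D1 * (1 + 2 * c1_f / vac_f)
      vel <- vel + 2 * p$D1 * (diff(c2p) / delta) / vac_f
    }
    .transport(c1, Vold, Vnew, Dface, vel, delta, dt)
  }
  # discrete interface law: velocity from the bond flux evaluated through
  # the Young-Dupre ghost value at the face, with a second-order one-sided
  # derivative over the last two (end-of-step) cell centres and the face
  Gfun <- function(v_hat, c1n) {
    s_new <- s_old + v_hat * dt
    xs <- c(xi_c[(N - 1):N], 1) * s_new
    dc <- onesided_deriv_last(xs, c(c1n[(N - 1):N], c1_gamma))
    dPhi <- onesided_deriv_last(xs, c(Phi_c[(N - 1):N], Phi_face))
    v <- -p$D1 * (dc + c1_gamma * dPhi) / c1_gamma
    if (crowd) {
      dc2 <- onesided_deriv_last(xs, c(c2p[(N - 1):N], c2_face))
      v <- v - p$D1 * 2 * (dc + dc2) / vacc_face
    }
    v
  }
  # implicit coupling: solve the fixed point v = G(c^{n+1}(v)) by secant
  # (explicit evaluation is stiff: the ghost gradient over the half-cell
  # reacts strongly to the compression that v itself produces)
  gres <- function(v_hat) {
    c1n <- solve_c1(v_hat)
    if (is.null(c1n)) return(NULL)
    v_hat - Gfun(v_hat, c1n)
  }
  v0 <- v_prev
  g0 <- gres(v0)
  if (is.null(g0)) return(list(ok = FALSE, why = "interface crossed origin"))
  vscale <- max(abs(v0 - g0), p$D1 / s_old)
  tol_v <- 3e-5 * vscale
  if (abs(g0) < tol_v) {          # warm start already converged
    v1 <- v0
  } else {
    v1 <- v0 - g0                 # first Picard update
    g1 <- gres(v1)
    if (is.null(g1)) return(list(ok = FALSE, why = "interface crossed origin"))
    ok <- abs(g1) < tol_v
    for (it in 1:30) {
      if (ok) break
      dg <- g1 - g0
      if (abs(dg) < 1e-300) break
      v2 <- v1 - g1 * (v1 - v0) / dg
      g2 <- gres(v2)
      if (is.null(g2)) return(list(ok = FALSE, why = "interface crossed origin"))
      v0 <- v1; g0 <- g1
      v1 <- v2; g1 <- g2
      ok <- abs(g1) < tol_v
    }
    if (!ok && abs(g1) > 1e-3 * vscale) {
      return(list(ok = FALSE, why = "interface velocity iteration stalled"))
    }
  }
  v_hat <- v1
  c1_new <- solve_c1(v_hat)
  s_new <- s_old + v_hat * dt

  # free binders on the composite grid [0, s_hat] + [s_hat, L0]
  M <- g$M
  eta_c <- g$outer$centers
  eta_f <- g$outer$faces
  Lo_old <- p$L0 - s_old
  Lo_new <- p$L0 - s_new
  centers_new <- c(xi_c * s_new, s_new + eta_c * Lo_new)
  Vold2 <- c(g$patch$dxi * s_old, g$outer$dxi * Lo_old)
  Vnew2 <- c(g$patch$dxi * s_new, g$outer$dxi * Lo_new)
  delta2 <- diff(centers_new)
  # face velocities: patch faces xi*v_hat (interior 2..N), the shared
  # interface face at v_hat, outer faces (1-eta)*v_hat
  w2 <- c(xi_f[2:N] * v_hat, v_hat, (1 - eta_f[2:M]) * v_hat)
  Dface2 <- rep(p$D2, N + M - 1)
  vel2 <- w2
  if (crowd) {
    c2all <- c2
    c1all <- c(c1, numeric(M))
    vacc2 <- p$cmax - c1all - c2all
    vac_f2 <- (vacc2[-1] + vacc2[-(N + M)]) / 2
    c2_f2 <- (c2all[-1] + c2all[-(N + M)]) / 2
    Dface2 <- p$D2 * (1 + c2_f2 / vac_f2)
    vel2 <- w2 + p$D2 * (diff(c1all) / delta2) / vac_f2
  }
  c2_new <- .transport(c2, Vold2, Vnew2, Dface2, vel2, delta2, dt)
  list(ok = TRUE, c1 = c1_new, c2 = c2_new, v_hat = v_hat)
}

.make_snapshot <- function(sim, state) {
  p <- sim$params
  g <- sim$grid
  s_hat <- state$s_hat
  s_patch <- g$patch$centers * s_hat
  s_outer <- s_hat + g$outer$centers * (p$L0 - s_hat)
  h <- state$h %||% numeric(g$N)
  pot <- chemical_potentials(pmax(state$c1, 0),
                             pmax(state$c2[1:g$N], 0), h, p)
  pot_out <- chemical_potentials(rep(p$c0, g$M),
                                 pmax(state$c2[-(1:g$N)], 0),
                                 numeric(g$M), p)
  rates <- rate_functions(h, p)
  rnet <- if (p$reactions_on && p$koff_bar > 0) {
    rates$kon * state$c2[1:g$N]^2 - rates$koff * state$c1
  } else numeric(g$N)
  list(t = state$t, s_hat = s_hat,
       s = s_patch, c1 = state$c1, h = h,
       mu1 = pot$mu1, mu2_patch = pot$mu2,
       s_c2 = c(s_patch, s_outer), c2 = state$c2,
       mu2 = c(pot$mu2, pot_out$mu2),
       rnet = rnet, theta = state$theta, v_hat = state$v_hat)
}

#' @export
print.peel_trajectory <- function(x, ...) {
  n <- length(x$t)
  cat("<peel_trajectory>\n")
  cat(sprintf("  %d steps to t = %.4g s; status: %s\n", n, x$t[n], x$status))
  cat(sprintf("  s_hat: %.4g -> %.4g um; N1: %.4g -> %.4g (x l_lat)\n",
              x$params$s_hat0 * 1e6, x$s_hat[n] * 1e6,
              x$N1[1], x$N1[n]))
  if (is.finite(x$t_fail)) cat(sprintf("  t_fail = %.4g s\n", x$t_fail))
  cat(sprintf("  %d snapshots\n", length(x$snapshots)))
  invisible(x)
}

#' Export trajectory scalar series and kymographs to CSV
#'
#' Writes \code{<stem>_scalars.csv} (time series of interface position,
#' contact angle, interface velocity, bond and binder numbers) and, if
#' snapshots were recorded, \code{<stem>_kymo_c1.csv} and
#' \code{<stem>_kymo_c2.csv} (long-format space-time rasters of the
#' concentration fields, with chemical potentials and net reaction rate).
#'
#' @param traj a \code{peel_trajectory}.
#' @param stem output file stem (path without extension).
#' @return invisibly, the vector of files written.
#' @export
write_trajectory_csv <- function(traj, stem) {
  files <- character(0)
  f1 <- paste0(stem, "_scalars.csv")
  utils::write.csv(data.frame(t = traj$t, s_hat = traj$s_hat,
                              theta = traj$theta, v_hat = traj$v_hat,
                              N1 = traj$N1, N2 = traj$N2, dt = traj$dt),
                   f1, row.names = FALSE)
  files <- f1
  if (length(traj$snapshots)) {
    k1 <- do.call(rbind, lapply(traj$snapshots, function(sn) {
      data.frame(t = sn$t, s = sn$s, c1 = sn$c1, h = sn$h, mu1 = sn$mu1,
                 rnet = sn$rnet)
    }))
    k2 <- do.call(rbind, lapply(traj$snapshots, function(sn) {
      data.frame(t = sn$t, s = sn$s_c2, c2 = sn$c2, mu2 = sn$mu2)
    }))
    f2 <- paste0(stem, "_kymo_c1.csv")
    f3 <- paste0(stem, "_kymo_c2.csv")
    utils::write.csv(k1, f2, row.names = FALSE)
    utils::write.csv(k2, f3, row.names = FALSE)
    files <- c(files, f2, f3)
  }
  invisible(files)
}
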