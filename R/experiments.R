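# Regime drivers and derived analyses: parameter presets for the three
# peeling regimes, travelling-front speed estimation, failure-time force
# sweeps, power-law strength fits, similarity-collapse diagnostics.

#' Parameter presets for the peeling regimes
#'
#' Returns a \code{\link{peel_params}} object preset for one of the
#' regimes: \describe{
#'   \item{diffusion}{long-lived mobile bonds: reactions off
#'     (koff_bar = 0), D2 = 2*D1 = 0.5 um^2/s, non-compliant.}
#'   \item{reaction}{short-lived slow bonds: koff_bar = 10/s, diffusivities
#'     reduced about 1000-fold (D1 = D2/2 = 0.25e-3 um^2/s), compliant
#'     slip bonds with f_beta = 4*f_gamma, constant contact angle.}
#'   \item{mixed}{short-lived mobile bonds: koff_bar = 10/s,
#'     D2 = 2*D1 = 0.5 um^2/s, compliant ideal bonds.}
#'   \item{crowding}{mixed regime with a finite crowding limit
#'     \code{cmax} (default 5*c0).}
#' }
#'
#' @param regime one of "diffusion", "reaction", "mixed", "crowding".
#' @param ... overrides passed to \code{\link{peel_params}}.
#' @return a \code{peel_params} object.
#' @export
regime_params <- function(regime = c("diffusion", "reaction", "mixed",
                                     "crowding"), ...) {
  regime <- match.arg(regime)
  base <- list(...)
  defaults <- switch(regime,
    diffusion = list(koff_bar = 0, reactions_on = FALSE,
                     D1 = 0.25e-12, D2 = 0.5e-12, compliant = FALSE),
    reaction = list(koff_bar = 10, reactions_on = TRUE,
                    D1 = 0.25e-15, D2 = 0.5e-15, compliant = TRUE,
                    f_beta = 4 * sqrt(2.5e-4 * 4.11e-21),
                    constant_theta = TRUE),
    mixed = list(koff_bar = 10, reactions_on = TRUE,
                 D1 = 0.25e-12, D2 = 0.5e-12, compliant = TRUE,
                 f_beta = Inf),
    crowding = list(koff_bar = 10, reactions_on = TRUE,
                    D1 = 0.25e-12, D2 = 0.5e-12, compliant = TRUE,
                    f_beta = Inf, crowding = TRUE, cmax = 5 * 2.5e15))
  args <- utils::modifyList(defaults, base)
  do.call(peel_params, args)
}

#' Estimate the travelling-front speed from a trajectory
#'
#' Fits a least-squares line to the interface position s_hat(t) on the
#' longest trailing window with R^2 >= \code{r2_min}, excluding the
#' initial transient (first \code{skip} fraction of the run). Travelling
#' decohesion fronts have constant interface velocity, so an accepted
#' estimate requires an essentially perfect linear tail.
#'
#' @param traj a \code{peel_trajectory}, or a list with numeric \code{t}
#'   and \code{s_hat}.
#' @param r2_min minimum R^2 for an accepted window (default 0.999).
#' @param skip fraction of the record always excluded at the start.
#' @return object of class \code{peel_front_speed}: \code{v_hat} (m/s,
#'   signed), \code{window} (= c(t_a, t_b)), \code{r_squared},
#'   \code{v_over_v0} (NA when the trajectory carries no scales).
#' @export
estimate_front_speed <- function(traj, r2_min = 0.999, skip = 0.2) {
  t <- traj$t
  s <- traj$s_hat
  n <- length(t)
  if (n < 10) stop("trajectory too short for a front-speed fit", call. = FALSE)
  i_min <- max(3L, ceiling(skip * n))
  fit_window <- function(i0) {
    idx <- i0:n
    f <- stats::lm.fit(cbind(1, t[idx]), s[idx])
    ssr <- sum(f$residuals^2)
    sst <- sum((s[idx] - mean(s[idx]))^2)
    list(slope = f$coefficients[2], r2 = if (sst > 0) 1 - ssr / sst else 1)
  }
  # expand the trailing window from the end until R^2 drops below r2_min
  starts <- unique(round(seq(i_min, n - 9, length.out = min(60, n - 9 - i_min + 2))))
  best <- NULL
  for (i0 in starts) {
    f <- fit_window(i0)
    if (f$r2 >= r2_min && (is.null(best) || i0 < best$i0)) {
      best <- c(f, list(i0 = i0))
    }
  }
  if (is.null(best)) {
    stop("no travelling regime detected: no trailing window reaches R^2 >= ",
         r2_min, call. = FALSE)
  }
  # report the slope from the trailing half of the qualifying window: any
  # residual transient bleed at the window start biases the full-window
  # slope but is negligible in its tail (exact for truly linear tracks)
  i_half <- max(best$i0, floor((best$i0 + n) / 2))
  slope <- if (n - i_half >= 9) fit_window(i_half)$slope else best$slope
  v0 <- if (!is.null(traj$scales)) traj$scales$v0 else NA_real_
  out <- list(v_hat = unname(slope),
              window = c(t[best$i0], t[n]),
              r_squared = best$r2,
              v_over_v0 = unname(abs(slope)) / v0)
  class(out) <- "peel_front_speed"
  out
}

#' @export
print.peel_front_speed <- function(x, ...) {
  cat(sprintf("<peel_front_speed> v_hat = %.4g nm/s on [%.3g, %.3g] s (R^2 = %.5f)",
              x$v_hat * 1e9, x$window[1], x$window[2], x$r_squared))
  if (is.finite(x$v_over_v0)) cat(sprintf("; |v|/v0 = %.3g", x$v_over_v0))
  cat("\n")
  invisible(x)
}

#' Failure-time force sweep
#'
#' Runs one peeling simulation per applied force and records the time to
#' complete failure (Inf for runs that arrest or do not fail before
#' \code{t_end}). Results are cached in \code{cache_dir} keyed by a hash of
#' the configuration, so re-running an identical sweep performs no new
#' simulations.
#'
#' @param params a \code{\link{peel_params}} object (force is overridden
#'   per run).
#' @param force_list applied forces as F/gamma values.
#' @param t_end per-run time cap, s.
#' @param resolution grid-resolution multiplier passed to
#'   \code{\link{run_peeling}}.
#' @param cache_dir directory for cached results, or NULL to disable.
#' @param verbose print per-run progress.
#' @param ... further arguments to \code{\link{run_peeling}}.
#' @return data.frame with columns \code{F_over_gamma}, \code{t_fail},
#'   \code{status}.
#' @export
sweep_failure_times <- function(params, force_list, t_end,
                                resolution = 1, cache_dir = NULL,
                                verbose = FALSE, ...) {
  res <- data.frame(F_over_gamma = force_list, t_fail = NA_real_,
                    status = NA_character_)
  for (i in seq_along(force_list)) {
    p_i <- params
    p_i$F_over_gamma <- force_list[i]
    key <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      cfg <- c(unlist(p_i), t_end = t_end, resolution = resolution)
      key <- file.path(cache_dir, paste0(
        "sweep_", substr(paste(
          format(sum(cumsum(as.numeric(
            serialize(cfg, NULL, ascii = TRUE)))) %% 2^31, scientific = FALSE),
          collapse = ""), 1, 18), "_", i, ".csv"))
    }
    if (!is.null(key) && file.exists(key)) {
      cached <- utils::read.csv(key)
      res$t_fail[i] <- cached$t_fail
      res$status[i] <- cached$status
      next
    }
    tr <- tryCatch(
      run_peeling(p_i, t_end = t_end, resolution = resolution, ...),
      error = function(e) NULL)
    if (is.null(tr)) {
      res$status[i] <- "error"
      res$t_fail[i] <- NA_real_
    } else {
      res$t_fail[i] <- tr$t_fail
      res$status[i] <- tr$status
    }
    if (!is.null(key)) {
      utils::write.csv(res[i, ], key, row.names = FALSE)
    }
    if (verbose) {
      message(sprintf("  F/gamma = %.3g -> t_fail = %.4g s (%s)",
                      force_list[i], res$t_fail[i], res$status[i]))
    }
  }
  res
}

#' Power-law strength fit of failure times
#'
#' Fits the adhesion-strength law \code{t_fail = A * (F - F_c)^a} to a
#' force sweep by nonlinear least squares in log-log space,
#' \code{log(t_fail) = log(A) + a*log(F - F_c)}, with the critical force
#' F_c free. Levenberg-Marquardt with 5 jittered multi-starts
#' (deterministic given \code{seed}); the best-residual fit is returned.
#' Forces within 1% of the running F_c estimate are excluded to avoid
#' leverage blow-up.
#'
#' @param forces applied forces (any consistent units, e.g. F/gamma).
#' @param t_fail failure times, s; only finite entries are fitted
#'   (>= 5 required).
#' @param seed integer seed for the multi-start jitter.
#' @return object of class \code{peel_strength_fit}: \code{a}, \code{F_c},
#'   \code{A}, \code{cov} (fit covariance), \code{forces}, \code{t_fail},
#'   \code{residual}.
#' @export
fit_power_law <- function(forces, t_fail, seed = 1L) {
  keep <- is.finite(t_fail) & is.finite(forces)
  forces <- forces[keep]
  t_fail <- t_fail[keep]
  if (length(forces) < 5) {
    stop("need >= 5 finite failure times for a power-law fit", call. = FALSE)
  }
  o <- order(forces)
  forces <- forces[o]
  t_fail <- t_fail[o]
  lt <- log(t_fail)
  Fmin <- min(forces)
  # initial exponent/prefactor from the two extreme points at Fc0
  Fc0 <- 0.98 * Fmin
  a0 <- (lt[length(lt)] - lt[1]) /
    (log(forces[length(forces)] - Fc0) - log(forces[1] - Fc0))
  if (!is.finite(a0) || a0 >= 0) a0 <- -2
  set.seed(seed)
  jit <- cbind(Fc = Fc0 * c(1, stats::runif(4, 0.85, 0.999)),
               a = a0 * c(1, stats::runif(4, 0.6, 1.6)))
  best <- NULL
  for (j in seq_len(nrow(jit))) {
    Fc_j <- unname(jit[j, "Fc"])
    a_j <- unname(jit[j, "a"])
    lA_j <- mean(lt - a_j * log(forces - Fc_j))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        lt ~ lA + a * log(forces - Fc),
        start = list(lA = lA_j, a = a_j, Fc = Fc_j),
        upper = c(lA = Inf, a = 0, Fc = 0.999 * Fmin),
        lower = c(lA = -Inf, a = -10, Fc = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("power-law fit failed to converge from all starts", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  # drop points within 1% of the fitted Fc and refit once if any
  close_pts <- forces < cf[["Fc"]] * 1.01
  if (any(close_pts) && sum(!close_pts) >= 5) {
    return(fit_power_law(forces[!close_pts], t_fail[!close_pts], seed = seed))
  }
  cov <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  out <- list(a = unname(cf[["a"]]), F_c = unname(cf[["Fc"]]),
              A = exp(unname(cf[["lA"]])), cov = cov,
              forces = forces, t_fail = t_fail, residual = best$rss)
  class(out) <- "peel_strength_fit"
  out
}

#' @export
print.peel_strength_fit <- function(x, ...) {
  cat(sprintf("<peel_strength_fit> t_fail = %.3g * (F - %.4g)^(%.3g); RSS = %.3g (%d points)\n",
              x$A, x$F_c, x$a, x$residual, length(x$forces)))
  invisible(x)
}

#' Similarity-collapse diagnostic for the diffusion-dominated regime
#'
#' Rescales the bond-concentration snapshots of a trajectory into the
#' similarity variable x/sqrt(tau) and measures the maximum deviation from
#' the analytic Stefan profile, normalized by the profile amplitude
#' |U - 1|.
#'
#' @param traj a \code{peel_trajectory} with snapshots, run in
#'   constant-theta, reactions-off, non-compliant mode.
#' @param U driving parameter of the run.
#' @return list with \code{max_dev} (worst normalized deviation over
#'   snapshots), \code{per_snapshot} data.frame, and \code{lambda}.
#' @export
similarity_collapse <- function(traj, U) {
  stopifnot(length(traj$snapshots) > 0)
  lam <- lambda_of_U(U)
  p <- traj$params
  tau1 <- traj$scales$tau_diff1
  C0 <- traj$equilibrium$C0
  rows <- lapply(traj$snapshots, function(sn) {
    tau <- sn$t / tau1
    if (tau <= 0) return(NULL)
    x <- sn$s / p$s_hat0 - 1
    u_num <- sn$c1 / C0 - U
    u_ref <- similarity_solution(x, tau, U, lam)
    # restrict to the patch side of the front where the layer lives
    data.frame(tau = tau, dev = max(abs(u_num - u_ref)) / abs(U - 1))
  })
  per <- do.call(rbind, rows)
  list(max_dev = max(per$dev), per_snapshot = per, lambda = lam)
}

#' Arrest diagnostic
#'
#' A run is considered arrested when, over the trailing fraction of the
#' record, the relative change of the patch half-size stays below
#' \code{tol_s} and (if a final state is available) the chemical
#' potentials satisfy |mu1 - 2*mu2| < tol_mu * |mu2_0| over the patch,
#' i.e. the patch has reached a fully equilibrated stable configuration.
#'
#' @param traj a \code{peel_trajectory}.
#' @param window trailing fraction of the record to examine.
#' @param tol_s relative s_hat drift threshold.
#' @param tol_mu chemical-potential equilibration threshold (x mu2_0).
#' @return list with logical \code{arrested}, \code{s_drift},
#'   \code{mu_gap}.
#' @export
is_arrested <- function(traj, window = 0.25, tol_s = 1e-4, tol_mu = 1e-2) {
  n <- length(traj$t)
  idx <- max(1, floor((1 - window) * n)):n
  s_drift <- (max(traj$s_hat[idx]) - min(traj$s_hat[idx])) /
    traj$s_hat[idx[1]]
  mu_gap <- NA_real_
  st <- traj$state
  if (!is.null(st$c1) && is.finite(traj$equilibrium$mu2_0)) {
    p <- traj$params
    h <- st$h %||% numeric(length(st$c1))
    pot <- chemical_potentials(pmax(st$c1, 1e-300 * p$c0),
                               pmax(st$c2[seq_along(st$c1)], 1e-300 * p$c0),
                               h, p)
    mu_gap <- max(abs(pot$mu1 - 2 * pot$mu2)) / abs(traj$equilibrium$mu2_0)
  }
  list(arrested = is.finite(traj$t_fail) == FALSE && s_drift < tol_s &&
         (is.na(mu_gap) || mu_gap < tol_mu),
       s_drift = s_drift, mu_gap = mu_gap)
}
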