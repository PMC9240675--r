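# YAML configuration files: one table per module, unknown keys are hard
# errors. Used by the command-line driver and for reproducible run setups.

.config_schema <- list(
  parameters = c("kBT", "kappa", "gamma", "k", "f_beta", "D1", "D2",
                 "koff_bar", "Kbar", "c0", "cmax", "R0", "s_hat0", "L0",
                 "F_over_gamma", "l_lat", "alpha"),
  modes = c("compliant", "crowding", "reactions_on", "constant_theta",
            "regime"),
  run = c("t_end", "theta_fixed_deg", "s_min", "resolution", "snap_times",
          "max_steps", "step_tol", "seed"),
  sweep = c("forces", "t_end", "resolution", "cache_dir")
)

#' Read a run configuration from YAML
#'
#' The configuration has one section per concern: \code{parameters}
#' (physical constants; any subset, the rest take package defaults),
#' \code{modes} (switches or a \code{regime} preset name), \code{run}
#' (integration controls) and \code{sweep} (force sweeps). Unknown
#' sections or keys are hard errors, not warnings.
#'
#' @param path path to a YAML file.
#' @return list with \code{params} (a \code{\link{peel_params}}), and the
#'   \code{run} / \code{sweep} sections as lists.
#' @export
read_peel_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad_sections <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_sections)) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  modes <- cfg$modes %||% list()
  regime <- modes$regime
  modes$regime <- NULL
  args <- c(cfg$parameters %||% list(), modes)
  params <- if (!is.null(regime)) {
    do.call(regime_params, c(list(regime = regime), args))
  } else {
    do.call(peel_params, args)
  }
  list(params = params, run = cfg$run %||% list(), sweep = cfg$sweep %||% list())
}
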