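# internal numerical helpers

# error function via the exact normal-CDF identity (no series approximation)
erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent header naming the offending field
fail_field <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

check_positive <- function(value, field, allow_inf = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    fail_field(field, "must be a single finite number")
  }
  if (!allow_inf && !is.finite(value)) fail_field(field, "must be finite")
  if (value <= 0) fail_field(field, "must be strictly positive")
  invisible(value)
}

# trapezoidal quadrature on a (possibly non-uniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# second-order one-sided derivative at the last point of a non-uniform grid
onesided_deriv_last <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L)
  h1 <- x[n] - x[n - 1L]
  h2 <- x[n - 1L] - x[n - 2L]
  # three-point backward formula, second order on non-uniform spacing
  a <- h1 / (h2 * (h1 + h2))
  b <- -(h1 + h2) / (h1 * h2)
  c <- (2 * h1 + h2) / (h1 * (h1 + h2))
  a * y[n - 2L] + b * y[n - 1L] + c * y[n]
}

# geometric grading: distances from a refined point, spacing dx_min at the
# point growing by `ratio` until dx_max, covering length L. Returns the
# sorted vector of offsets in (0, L], always ending exactly at L.
graded_offsets <- function(L, dx_min, dx_max, ratio = 1.15) {
  stopifnot(L > 0, dx_min > 0, dx_max >= dx_min, ratio > 1)
  offs <- numeric(0)
  pos <- 0
  dx <- dx_min
  while (pos < L) {
    pos <- pos + dx
    offs <- c(offs, pos)
    dx <- min(dx * ratio, dx_max)
  }
  offs[length(offs)] <- L
  # guard against a degenerate final interval
  n <- length(offs)
  if (n >= 2L && (offs[n] - offs[n - 1L]) < 0.25 * (offs[n - 1L] - if (n >= 3L) offs[n - 2L] else 0)) {
    offs <- offs[-(n - 1L)]
  }
  offs
}
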