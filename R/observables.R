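#' Substrate consumption rate
#'
#' Total rate of substrate burning, `b = nu' * integral a_c(x) dx`, using
#' the same quadrature as the force integral.  Tiny negative excursions of
#' the solved field are clipped to zero before integrating.
#'
#' @param a_c Complex concentration per node (a0 units).
#' @param grid A [make_grid()] object.
#' @param nu_p Burn rate (r units).
#' @param quadrature Quadrature rule.
#' @return Consumption rate (a0 sigma per tau), non-negative.
#' @export
consumption_rate <- function(a_c, grid, nu_p,
                             quadrature = c("rectangle", "trapezoid")) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(grid, "bbr_grid"))
  nu_p * sum(pmax(a_c, 0) * quad_weights(grid, quadrature))
}

#' Stokes efficiency
#'
#' Ratio of the power dissipated against viscous drag to the rate of
#' chemical free-energy consumption.  In dimensionless form
#' `eta = v^2 / (dg * b)` with `dg` the free energy per burned substrate
#' in thermal units.  A stalled motor (`v = 0`) has zero efficiency by
#' definition even though it keeps burning substrate; `b = 0` with
#' `v != 0` is impossible (motion requires bound complex) and raises an
#' error.
#'
#' @param v Velocity (sigma per tau).
#' @param b Consumption rate (a0 sigma per tau).
#' @param dg Free energy per burned substrate (kBT units).
#' @return Dimensionless efficiency, non-negative.  Vectorized over `v`
#'   and `b`.
#' @export
stokes_efficiency <- function(v, b, dg) {
  if (dg <= 0) stop("stokes_efficiency(): dg must be positive")
  if (any(b < 0)) stop("stokes_efficiency(): negative consumption rate")
  if (any(b == 0 & v != 0)) {
    stop("stokes_efficiency(): b = 0 with v != 0 is an impossible state")
  }
  ifelse(v == 0, 0, v^2 / (dg * b))
}

#' Linear fit of consumption rate against velocity
#'
#' Across steady states the consumption rate is closely linear in the
#' velocity, `b ~ slope * v + b_stall`, with a positive intercept set by
#' the stall consumption.  Ordinary least squares of `b` on `v` with a
#' free intercept.
#'
#' @param v,b Numeric vectors of steady-state velocities and consumption
#'   rates (at least 3 points; `v` must not be constant).
#' @return An object of class `linear_fit` with `slope`, `intercept` and
#'   `r_squared`.
#' @export
fit_b_vs_v <- function(v, b) {
  if (length(v) < 3 || length(b) != length(v)) {
    stop("fit_b_vs_v(): need at least 3 (v, b) pairs")
  }
  if (stats::var(v) == 0) {
    stop("fit_b_vs_v(): all velocities equal; fit is degenerate")
  }
  fit <- stats::lm(b ~ v)
  ss_tot <- sum((b - mean(b))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("b = %.5g * v + %.5g   (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Normalize a sequence by its maximum
#'
#' @param values Numeric vector with at least one strictly positive entry.
#' @return `values / max(values)`; the maximum maps to exactly 1.
#' @export
normalize_by_max <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) {
    stop("normalize_by_max(): need at least one strictly positive value")
  }
  values / m
}
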