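#' Uniform spatial grid for the substrate fields
#'
#' The two concentration fields live on a fixed uniform grid; the hub
#' position is a continuous coordinate and is never snapped to a node.
#' The default spacing of 0.1 sigma resolves the unit-width Gaussian
#' binding kernel comfortably.
#'
#' @param x_min,x_max Domain edges (sigma units); the span must be at
#'   least 40 sigma so that the fields can relax to their bulk value away
#'   from the hub.
#' @param dx Node spacing (sigma units), default 0.1.
#' @return An object of class `bbr_grid` with fields `x0`, `dx`, `n` and
#'   the node positions `x`.
#' @examples
#' g <- make_grid(-50, 350)
#' g$n   # 4001
#' @export
make_grid <- function(x_min, x_max, dx = 0.1) {
  if (!is.finite(dx) || dx <= 0) stop("make_grid(): dx must be positive")
  if (x_max - x_min < 40) {
    stop("make_grid(): domain must span at least 40 sigma")
  }
  n <- as.integer(round((x_max - x_min) / dx)) + 1L
  # nodes are built symmetrically about the domain centre, so mirror-image
  # nodes are exact floating-point negatives of each other; a hub sitting
  # exactly at the centre of a symmetric state then feels exactly zero force
  xc <- (x_min + x_max) / 2
  ctr <- (n - 1) / 2
  structure(list(x0 = x_min, xc = xc, dx = dx, n = n,
                 x = (seq_len(n) - 1L - ctr) * dx + xc),
            class = "bbr_grid")
}

#' @export
print.bbr_grid <- function(x, ...) {
  cat(sprintf("BBR grid: %d nodes on [%g, %g], dx = %g sigma\n",
              x$n, x$x0, x$x[x$n], x$dx))
  invisible(x)
}

#' Full state of the motor system
#'
#' @param xh Hub position (sigma units), a continuous coordinate.
#' @param a_s Surface-bound substrate concentration at each node (a0 units).
#' @param a_c Hub-bound complex concentration at each node (a0 units).
#' @param grid The [make_grid()] the fields live on.
#' @return An object of class `field_state`.
#' @export
field_state <- function(xh, a_s, a_c, grid) {
  stopifnot(inherits(grid, "bbr_grid"))
  if (length(a_s) != grid$n || length(a_c) != grid$n) {
    stop("field_state(): field lengths must match the grid")
  }
  if (!is.finite(xh) || any(!is.finite(a_s)) || any(!is.finite(a_c))) {
    stop("field_state(): state must be finite")
  }
  if (any(a_s < 0) || any(a_c < 0)) {
    stop("field_state(): concentrations must be non-negative")
  }
  structure(list(xh = xh, a_s = a_s, a_c = a_c), class = "field_state")
}

#' Gaussian complex-formation kernel
#'
#' Arrhenius rate factor for a tether fluctuating to reach the hub:
#' the elastic energy of an excursion of length `x - xh` is
#' `(x - xh)^2 / 2` in thermal units, so the formation rate is suppressed
#' by `exp(-(x - xh)^2 / 2)`.
#'
#' @param x Node position(s) (sigma units).
#' @param xh Hub position (sigma units).
#' @return Dimensionless rate factor in (0, 1].
#' @export
binding_kernel <- function(x, xh) {
  exp(-(x - xh)^2 / 2)
}

#' Elastic drift velocity of the hub
#'
#' Overdamped force balance: every bound complex at `x` pulls the hub with
#' a linear spring, so the dimensionless hub velocity is
#' `-integral (xh - x) a_c(x) dx`.  Positive when the complex mass lies
#' ahead of the hub.
#'
#' @param a_c Complex concentration per node (a0 units).
#' @param grid A [make_grid()] object.
#' @param xh Hub position (sigma units).
#' @param quadrature `"rectangle"` (default, matches the uniform-grid
#'   discretization) or `"trapezoid"`.
#' @return Hub velocity (sigma per tau).
#' @export
hub_drift <- function(a_c, grid, xh, quadrature = c("rectangle", "trapezoid")) {
  quadrature <- match.arg(quadrature)
  if (any(!is.finite(a_c))) stop("hub_drift(): non-finite complex field")
  w <- quad_weights(grid, quadrature)
  -sum((xh - grid$x) * a_c * w)
}

quad_weights <- function(grid, quadrature) {
  w <- rep(grid$dx, grid$n)
  if (quadrature == "trapezoid") {
    w[1] <- w[grid$n] <- grid$dx / 2
  }
  w
}

#' Constant substrate replenishment source
#'
#' With the well-mixed buffer at steady state with the surface, free
#' substrate rebinds the surface at the constant rate
#' `koff' * atot / (1 + K)` per unit length, independent of space and
#' time.
#'
#' @param params A [dimensionless_params()] object.
#' @return Source term (a0 per tau).
#' @export
replenishment_rate <- function(params) {
  stopifnot(inherits(params, "dimensionless_params"))
  if (params$koff_p == 0) return(0)
  params$koff_p * params$atot / (1 + params$K)
}

#' Bulk steady state of the surface-bound substrate
#'
#' Far from the hub the surface field settles at
#' `a_s* = atot / (1 + K)`: the closed system partitions substrate between
#' surface and buffer according to the turnover equilibrium constant `K`
#' alone.
#'
#' @param atot Total substrate concentration (a0 units).
#' @param K Turnover equilibrium constant `koff/kon`.
#' @return Bulk surface concentration (a0 units).
#' @export
surface_steady_state <- function(atot, K) {
  if (K < 0) stop("surface_steady_state(): K must be non-negative")
  atot / (1 + K)
}

# Default ceiling on the force-amplified unbinding rate omega'*exp(delta*|d|)
# (formation-rate units).  Far from the hub the Bell factor grows without
# bound while the complex held there is kernel-suppressed to negligible
# mass; uncapped rates make the kinetics arbitrarily stiff without changing
# any observable.  Rates at the cap are instantaneous compared with every
# other process in the model.
BELL_RATE_CAP <- 500

#' Time derivatives of the full state
#'
#' Right-hand side of the dimensionless equations of motion.  At each node
#' with kernel value `g = exp(-(x - xh)^2/2)`:
#' \deqn{da_c/dtau = g a_s - nu' a_c - omega' e^{delta |xh - x|} a_c}
#' \deqn{da_s/dtau = koff' atot/(1+K) - koff' a_s - g a_s
#'                   + omega' e^{delta |xh - x|} a_c}
#' and the hub moves with the elastic drift [hub_drift()].  With
#' `omega_p = 0` the Bell unbinding terms vanish and the pure burnt-bridge
#' kinetics remain.  This is the reference R implementation; the
#' integrator evaluates an equivalent compiled version.
#'
#' @param state A [field_state()].
#' @param grid A [make_grid()] object.
#' @param params A [dimensionless_params()] object.
#' @param quadrature Quadrature rule for the force integral.
#' @param bell_rate_cap Ceiling on the force-amplified unbinding rate
#'   `omega_p * exp(delta |xh - x|)` (formation-rate units).  The Bell
#'   factor grows without bound far from the hub while the complex there
#'   is kernel-suppressed to negligible mass; the cap bounds the stiffness
#'   of the kinetics without changing any observable.
#' @return List with components `dxh`, `da_s`, `da_c`.
#' @export
rhs <- function(state, grid, params, quadrature = c("rectangle", "trapezoid"),
                bell_rate_cap = BELL_RATE_CAP) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(params, "dimensionless_params"))
  g <- binding_kernel(grid$x, state$xh)
  bell <- if (params$omega_p > 0) {
    pmin(params$omega_p *
           exp(pmin(params$delta * abs(state$xh - grid$x), 700)),
         bell_rate_cap)
  } else {
    0
  }
  form <- g * state$a_s
  unbind <- bell * state$a_c
  da_c <- form - params$nu_p * state$a_c - unbind
  da_s <- replenishment_rate(params) - params$koff_p * state$a_s - form + unbind
  out <- list(dxh = hub_drift(state$a_c, grid, state$xh, quadrature),
              da_s = da_s, da_c = da_c)
  if (any(!is.finite(da_s)) || any(!is.finite(da_c)) || !is.finite(out$dxh)) {
    bad <- which(!is.finite(da_s) | !is.finite(da_c))[1]
    stop(sprintf("rhs(): non-finite derivative (first bad node %s)",
                 ifelse(is.na(bad), "hub", bad)))
  }
  out
}

#' Independent steady-state consumption rate of a stalled hub
#'
#' For a stationary hub with no complex unbinding the fields admit a
#' closed-form stationary solution: `a_s*(x) = s / (koff' + g(x))` with
#' source `s = koff' atot / (1 + K)` and `g(x) = exp(-x^2/2)`, and every
#' complex formed is eventually burned, so the consumption rate is
#' \deqn{b = s \int g(x) / (koff' + g(x)) dx}
#' independent of the burn rate.  Evaluated here by adaptive quadrature
#' ([stats::integrate()]) over the whole line, providing an oracle that is
#' independent of the time-stepping simulator.
#'
#' @param params A [dimensionless_params()] object with `omega_p = 0` and
#'   `koff_p > 0`.
#' @return Stalled steady-state consumption rate (a0 sigma per tau).
#' @export
stalled_consumption_oracle <- function(params) {
  stopifnot(inherits(params, "dimensionless_params"))
  if (params$omega_p != 0) {
    stop("stalled_consumption_oracle(): only supported for omega_p = 0")
  }
  if (params$koff_p <= 0) {
    stop("stalled_consumption_oracle(): requires koff_p > 0")
  }
  s <- replenishment_rate(params)
  k <- params$koff_p
  integrand <- function(x) {
    g <- exp(-x^2 / 2)
    g / (k + g)
  }
  # integrand decays like g/koff'; [-60, 60] leaves a tail < 1e-10 relative
  q <- stats::integrate(integrand, -60, 60, rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 500L)
  s * q$value
}
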