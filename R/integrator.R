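#' Time-integration and steady-state settings
#'
#' @param tau_end Integration horizon (tau units).  Runs exit earlier once
#'   the steady-state plateau test passes.
#' @param rel_tol,abs_tol Per-step error tolerances of the adaptive
#'   Runge-Kutta solver.
#' @param sample_interval Output cadence (tau units).
#' @param boundary_margin Minimum allowed hub-edge distance (sigma units,
#'   at least 10); the run stops with a flag if the hub gets closer to
#'   either domain edge.
#' @param stall_velocity_tol Absolute velocity below which a steady state
#'   is classified as stalled (sigma per tau).
#' @param steady_rel_tol Relative change of windowed means below which the
#'   run counts as converged.
#' @param steady_window Span of the plateau-assessment windows (tau units).
#' @return An object of class `integration_settings`.
#' @export
integration_settings <- function(tau_end = 500, rel_tol = 1e-6,
                                 abs_tol = 1e-9, sample_interval = 1,
                                 boundary_margin = 10,
                                 stall_velocity_tol = 1e-4,
                                 steady_rel_tol = 1e-3,
                                 steady_window = 50) {
  vals <- c(tau_end, rel_tol, abs_tol, sample_interval, boundary_margin,
            stall_velocity_tol, steady_rel_tol, steady_window)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("integration_settings(): all settings must be positive")
  }
  if (boundary_margin < 10) {
    stop("integration_settings(): boundary_margin must be at least 10 sigma")
  }
  structure(list(tau_end = tau_end, rel_tol = rel_tol, abs_tol = abs_tol,
                 sample_interval = sample_interval,
                 boundary_margin = boundary_margin,
                 stall_velocity_tol = stall_velocity_tol,
                 steady_rel_tol = steady_rel_tol,
                 steady_window = steady_window),
            class = "integration_settings")
}

#' Symmetry-breaking initial condition
#'
#' The surface-bound field starts at its bulk steady state
#' `atot / (1 + K)` everywhere except for a triangular (V-shaped) notch of
#' width `well_width` immediately behind the hub, which dips linearly to
#' `(1 - well_depth_fraction)` of the plateau at the notch centre.  The
#' notch emulates a patch of already-consumed track and breaks the
#' left-right symmetry so the hub starts moving forward; steady-state
#' results are insensitive to its shape.  With `well_depth_fraction = 0`
#' the state is exactly uniform and the hub stays put forever.  The
#' complex field starts empty.
#'
#' @param grid A [make_grid()] object.
#' @param params A [dimensionless_params()] object.
#' @param xh0 Initial hub position (sigma units).
#' @param well_width Notch width (sigma units).
#' @param well_depth_fraction Fractional depth of the notch in \[0, 1\];
#'   1 means the notch reaches zero concentration.
#' @return A [field_state()].
#' @export
initial_condition <- function(grid, params, xh0 = 0, well_width = 10,
                              well_depth_fraction = 1) {
  stopifnot(inherits(grid, "bbr_grid"), inherits(params, "dimensionless_params"))
  if (well_depth_fraction < 0 || well_depth_fraction > 1) {
    stop("initial_condition(): well_depth_fraction must lie in [0, 1]")
  }
  plateau <- surface_steady_state(params$atot, params$K)
  a_s <- rep(plateau, grid$n)
  if (well_depth_fraction > 0 && well_width > 0) {
    lo <- xh0 - well_width
    if (lo < grid$x0 || xh0 > grid$x[grid$n]) {
      stop("initial_condition(): triangular well must lie inside the domain")
    }
    mid <- xh0 - well_width / 2
    inside <- grid$x >= lo & grid$x <= xh0
    # V-shape: plateau at the edges, (1 - depth) * plateau at the centre
    frac <- 1 - well_depth_fraction * (1 - abs(grid$x[inside] - mid) / (well_width / 2))
    a_s[inside] <- plateau * frac
  }
  field_state(xh0, a_s, rep(0, grid$n), grid)
}

bbr_parms <- function(grid, params, quadrature, bell_rate_cap = BELL_RATE_CAP) {
  c(n = grid$n, xc = grid$xc, dx = grid$dx,
    nu_p = params$nu_p, koff_p = params$koff_p,
    src = replenishment_rate(params),
    omega_p = params$omega_p, delta = params$delta,
    trap = as.numeric(quadrature == "trapezoid"),
    bell_rate_cap = bell_rate_cap)
}

#' Integrate the motor dynamics
#'
#' Method-of-lines integration of the coupled hub/field equations with an
#' adaptive explicit Runge-Kutta 4(5) pair (Dormand-Prince, via
#' [deSolve::ode()]) and per-step error control.  The run proceeds in
#' windows of `steady_window` and exits early once the windowed means of
#' velocity and consumption have plateaued (relative change below
#' `steady_rel_tol`), or stops with a flag if the hub approaches either
#' domain edge closer than `boundary_margin`.  Velocity and consumption
#' are evaluated from the instantaneous right-hand side at every sample
#' time, never by differencing the trajectory.
#'
#' @param state0 Initial [field_state()].
#' @param grid A [make_grid()] object.
#' @param params A [dimensionless_params()] object.
#' @param settings An [integration_settings()] object.
#' @param quadrature Quadrature rule for the force/consumption integrals.
#' @param method [deSolve::ode()] method; default `"ode45"`.
#' @param bell_rate_cap Ceiling on the force-amplified unbinding rate; see
#'   [rhs()].
#' @param snapshots If `TRUE`, store the full fields at the end of every
#'   window.
#' @return An object of class `bbr_trajectory` with fields `times`,
#'   `xh_t`, `v_t`, `b_t`, `snapshots`, the final [field_state()], a
#'   `boundary_hit` flag, and the inputs for provenance.
#' @export
integrate_motor <- function(state0, grid, params,
                            settings = integration_settings(),
                            quadrature = c("rectangle", "trapezoid"),
                            method = "ode45", bell_rate_cap = BELL_RATE_CAP,
                            snapshots = FALSE) {
  quadrature <- match.arg(quadrature)
  stopifnot(inherits(state0, "field_state"), inherits(grid, "bbr_grid"),
            inherits(params, "dimensionless_params"),
            inherits(settings, "integration_settings"))
  if (length(state0$a_s) != grid$n) {
    stop("integrate_motor(): state and grid sizes disagree")
  }

  parms <- bbr_parms(grid, params, quadrature, bell_rate_cap)
  y <- c(state0$xh, state0$a_s, state0$a_c)
  n <- grid$n

  window <- settings$steady_window
  n_windows <- ceiling(settings$tau_end / window)
  lo_edge <- grid$x0 + settings$boundary_margin
  hi_edge <- grid$x[n] - settings$boundary_margin

  times <- xh_t <- v_t <- b_t <- numeric(0)
  snaps <- list()
  boundary_hit <- FALSE
  prev_means <- NULL
  converged_early <- FALSE
  t0 <- 0

  for (w in seq_len(n_windows)) {
    t1 <- min(t0 + window, settings$tau_end)
    tt <- seq(t0, t1, by = settings$sample_interval)
    if (length(tt) < 2) break
    sol <- deSolve::ode(y = y, times = tt, func = "bbr_derivs",
                        parms = parms, dllname = "bbrmotor",
                        initfunc = "bbr_initmod", nout = 2,
                        outnames = c("v", "b"), method = method,
                        rtol = settings$rel_tol, atol = settings$abs_tol,
                        maxsteps = 1e6)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol))) {
      stop(sprintf("integrate_motor(): solver failure near tau = %g", t0))
    }
    keep <- if (w == 1) seq_len(nrow(sol)) else seq(2, nrow(sol))
    xh_w <- sol[keep, 2]
    out_of_bounds <- xh_w < lo_edge | xh_w > hi_edge
    cut <- if (any(out_of_bounds)) which(out_of_bounds)[1] else length(keep)
    if (any(out_of_bounds)) boundary_hit <- TRUE
    sel <- keep[seq_len(cut)]
    times <- c(times, sol[sel, 1])
    xh_t <- c(xh_t, sol[sel, 2])
    v_t <- c(v_t, sol[sel, "v"])
    b_t <- c(b_t, sol[sel, "b"])
    y <- as.numeric(sol[sel[length(sel)], 1 + seq_len(2 * n + 1)])
    if (snapshots) {
      snaps[[length(snaps) + 1]] <- list(
        time = sol[sel[length(sel)], 1],
        a_s = pmax(y[1 + seq_len(n)], 0),
        a_c = pmax(y[1 + n + seq_len(n)], 0))
    }
    if (boundary_hit) break

    means <- c(mean(sol[keep, "v"]), mean(sol[keep, "b"]))
    if (!is.null(prev_means)) {
      dv <- rel_change(means[1], prev_means[1], settings$stall_velocity_tol)
      db <- rel_change(means[2], prev_means[2], settings$stall_velocity_tol)
      if (dv < settings$steady_rel_tol && db < settings$steady_rel_tol) {
        converged_early <- TRUE
      }
    }
    prev_means <- means
    t0 <- t1
    if (converged_early || t1 >= settings$tau_end) break
  }

  final <- field_state(y[1], pmax(y[1 + seq_len(n)], 0),
                       pmax(y[1 + n + seq_len(n)], 0), grid)
  structure(list(times = times, xh_t = xh_t, v_t = v_t, b_t = b_t,
                 snapshots = snaps, final_state = final,
                 boundary_hit = boundary_hit, params = params, grid = grid,
                 settings = settings, quadrature = quadrature),
            class = "bbr_trajectory")
}

# relative change with an absolute floor so that means near zero (stall)
# compare on an absolute scale instead of blowing up
rel_change <- function(a, b, floor_abs) {
  abs(a - b) / max(abs(a), abs(b), floor_abs)
}

#' @export
print.bbr_trajectory <- function(x, ...) {
  cat(sprintf("BBR trajectory: %d samples to tau = %g; xh %g -> %g\n",
              length(x$times), max(x$times), x$xh_t[1],
              x$xh_t[length(x$xh_t)]))
  if (x$boundary_hit) cat("  [run stopped at domain boundary]\n")
  invisible(x)
}

#' Extract the steady state from a trajectory
#'
#' Windowed-mean plateau test: the steady velocity and consumption are the
#' means over the final `steady_window` of the run, and the run counts as
#' converged when both means changed by less than `steady_rel_tol`
#' (relative) between the last two consecutive windows.  A converged run
#' with `|v_ss|` below `stall_velocity_tol` is classified as stalled and
#' assigned zero efficiency (substrate is still burned at stall, but no
#' useful work is done).  Runs whose velocity is still decaying are
#' reported with `converged = FALSE`, never extrapolated.
#'
#' @param traj A [integrate_motor()] trajectory.
#' @param settings Settings to use; defaults to those stored in `traj`.
#' @return An object of class `steady_state_result` with fields `v_ss`,
#'   `b_ss`, `eta`, `stalled`, `converged`, `tau_reached` and
#'   `boundary_hit`.
#' @export
find_steady_state <- function(traj, settings = NULL) {
  stopifnot(inherits(traj, "bbr_trajectory"))
  if (is.null(settings)) settings <- traj$settings
  if (length(traj$times) == 0) stop("find_steady_state(): empty trajectory")

  tmax <- max(traj$times)
  window <- settings$steady_window
  in_last <- traj$times > tmax - window
  in_prev <- traj$times > tmax - 2 * window & !in_last
  if (!any(in_last) || !any(in_prev)) {
    stop("find_steady_state(): trajectory shorter than two assessment windows")
  }
  v_ss <- mean(traj$v_t[in_last])
  b_ss <- mean(traj$b_t[in_last])
  dv <- rel_change(v_ss, mean(traj$v_t[in_prev]), settings$stall_velocity_tol)
  db <- rel_change(b_ss, mean(traj$b_t[in_prev]), settings$stall_velocity_tol)
  converged <- dv < settings$steady_rel_tol && db < settings$steady_rel_tol
  stalled <- abs(v_ss) <= settings$stall_velocity_tol
  eta <- if (stalled || b_ss <= 0) 0 else
    stokes_efficiency(v_ss, b_ss, traj$params$dg)

  # plateau onset: first window boundary from which successive windowed
  # means agree within tolerance
  tau_reached <- NA_real_
  edges <- seq(0, tmax - window, by = window)
  if (length(edges) >= 2) {
    wm <- vapply(edges, function(e) {
      sel <- traj$times > e & traj$times <= e + window
      c(mean(traj$v_t[sel]), mean(traj$b_t[sel]))
    }, numeric(2))
    for (i in seq_len(ncol(wm) - 1)) {
      if (rel_change(wm[1, i + 1], wm[1, i], settings$stall_velocity_tol) <
            settings$steady_rel_tol &&
          rel_change(wm[2, i + 1], wm[2, i], settings$stall_velocity_tol) <
            settings$steady_rel_tol) {
        tau_reached <- edges[i + 1]
        break
      }
    }
  }

  structure(list(v_ss = v_ss, b_ss = b_ss, eta = eta, stalled = stalled,
                 converged = converged, tau_reached = tau_reached,
                 boundary_hit = traj$boundary_hit),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf(
    "Steady state: v = %.5g, b = %.5g, eta = %.5g (%s%s)\n",
    x$v_ss, x$b_ss, x$eta,
    if (x$stalled) "stalled" else "moving",
    if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Export a trajectory as a tidy table
#'
#' @param traj A [integrate_motor()] trajectory.
#' @param path Optional CSV path; when given the table is also written.
#' @return A data frame with columns `tau`, `xh`, `v`, `b`.
#' @export
trajectory_table <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "bbr_trajectory"))
  df <- data.frame(tau = traj$times, xh = traj$xh_t, v = traj$v_t,
                   b = traj$b_t)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
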