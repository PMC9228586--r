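#' Run one simulation from parameters to steady state
#'
#' Convenience pipeline: build the grid and symmetry-breaking initial
#' condition, integrate to the plateau, extract the steady state and
#' return a one-row data frame (parameters + `v_ss`, `b_ss`, `eta`,
#' `stalled`, `converged`, `tau_reached`, `boundary_hit`, `flagged`).
#' `flagged` marks runs that neither converged nor stalled; sweep
#' summaries must not silently include them.  If the hub reaches the
#' domain edge before converging the run is retried with a doubled
#' forward domain (up to `max_extensions` times).
#'
#' @param params A [dimensionless_params()] object.
#' @param settings An [integration_settings()] object.
#' @param dx Grid spacing (sigma units).
#' @param domain_behind,domain_ahead Domain extent behind/ahead of the
#'   initial hub position (sigma units).
#' @param xh0 Initial hub position.
#' @param well_width,well_depth_fraction Triangular-well shape; a depth
#'   fraction of 0 gives the exactly symmetric (stalling) initial state.
#' @param quadrature Quadrature rule.
#' @param keep_trajectory If `TRUE` the trajectory is attached as
#'   attribute `"trajectory"`.
#' @param record_path Optional path for a JSON run record.
#' @param trajectory_csv Optional path for the tidy trajectory CSV.
#' @param max_extensions Maximum number of domain doublings after a
#'   boundary hit.
#' @return A one-row data frame (a "sweep row").
#' @examples
#' \donttest{
#' run_single(dimensionless_params(atot = 1, nu_p = 1))
#' }
#' @export
run_single <- function(params, settings = integration_settings(),
                       dx = 0.1, domain_behind = 50, domain_ahead = 300,
                       xh0 = 0, well_width = 10, well_depth_fraction = 1,
                       quadrature = "rectangle", keep_trajectory = FALSE,
                       record_path = NULL, trajectory_csv = NULL,
                       max_extensions = 2) {
  stopifnot(inherits(params, "dimensionless_params"))
  ahead <- domain_ahead
  for (attempt in seq_len(max_extensions + 1)) {
    grid <- make_grid(xh0 - domain_behind, xh0 + ahead, dx)
    state0 <- initial_condition(grid, params, xh0 = xh0,
                                well_width = well_width,
                                well_depth_fraction = well_depth_fraction)
    traj <- integrate_motor(state0, grid, params, settings,
                            quadrature = quadrature)
    ss <- find_steady_state(traj, settings)
    if (!traj$boundary_hit || ss$converged) break
    ahead <- ahead * 2
  }
  row <- data.frame(
    atot = params$atot, nu_p = params$nu_p, koff_p = params$koff_p,
    K = params$K, omega_p = params$omega_p, delta = params$delta,
    dg = params$dg,
    v_ss = ss$v_ss, b_ss = ss$b_ss, eta = ss$eta,
    stalled = ss$stalled, converged = ss$converged,
    tau_reached = ss$tau_reached, boundary_hit = ss$boundary_hit,
    flagged = !ss$converged && !ss$stalled
  )
  if (!is.null(record_path)) {
    write_run_record(record_path, params, settings, ss)
  }
  if (!is.null(trajectory_csv)) trajectory_table(traj, trajectory_csv)
  if (keep_trajectory) attr(row, "trajectory") <- traj
  row
}

#' Write a JSON run record
#'
#' Full resolved parameter set, integration settings and convergence flags
#' for provenance.
#'
#' @param path Output path.
#' @param params,settings,result The run's parameters, settings and
#'   [find_steady_state()] result.
#' @export
write_run_record <- function(path, params, settings, result) {
  rec <- list(params = unclass(params), settings = unclass(settings),
              result = unclass(result))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

build_params <- function(fixed, ...) {
  upd <- list(...)
  args <- list(atot = fixed$atot, nu_p = fixed$nu_p, koff_p = fixed$koff_p,
               kon_p = fixed$kon_p, omega_p = fixed$omega_p,
               delta = fixed$delta, dg = fixed$dg)
  args[names(upd)] <- upd
  do.call(dimensionless_params, args)
}

sweep_grid <- function(axes, fixed, run_args, verbose = TRUE) {
  combos <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))
  if (verbose) {
    message(sprintf("sweep: %d runs over {%s}", nrow(combos),
                    paste(names(axes), collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    p <- do.call(build_params, c(list(fixed), as.list(combos[i, , drop = FALSE])))
    do.call(run_single, c(list(params = p), run_args))
  })
  do.call(rbind, rows)
}

#' Sweep steady states over arbitrary parameter axes
#'
#' General sweep driver: one [run_single()] per point of the Cartesian
#' product of the supplied axes.  Axes may be any of `nu_p`, `atot`,
#' `koff_p`, `omega_p`, `delta`; re-running the same spec reproduces the
#' table bit for bit (the model is deterministic).
#'
#' @param axes Named list of numeric axis values.
#' @param fixed A [dimensionless_params()] object supplying the non-swept
#'   parameters.
#' @param verbose Announce the run count before executing.
#' @param ... Passed to [run_single()].
#' @return A data frame with one sweep row per grid point.
#' @export
parameter_sweep <- function(axes, fixed = dimensionless_params(),
                            verbose = TRUE, ...) {
  allowed <- c("nu_p", "atot", "koff_p", "omega_p", "delta", "dg")
  if (is.null(names(axes)) || !all(names(axes) %in% allowed)) {
    stop("parameter_sweep(): axes must be named among ",
         paste(allowed, collapse = ", "))
  }
  axes <- lapply(axes, function(v) as.numeric(unlist(v)))
  sweep_grid(axes, fixed, list(...), verbose)
}

#' Sweep steady-state velocity and consumption over burn rate and substrate
#'
#' One run per point of the (`nu_p`, `atot`) grid with everything else
#' held at `fixed`.  At fixed `atot` the steady velocity has an interior
#' maximum over the burn rate; at fixed `nu_p` it increases and saturates
#' with `atot`.
#'
#' @param nu_p,atot Numeric vectors of axis values (either may have
#'   length 1).
#' @param fixed A [dimensionless_params()] object supplying the
#'   non-swept parameters.
#' @param verbose Announce the run count before executing.
#' @param ... Passed to [run_single()].
#' @return A data frame with one sweep row per grid point.
#' @export
sweep_velocity_consumption <- function(nu_p = 1, atot = 1,
                                       fixed = dimensionless_params(),
                                       verbose = TRUE, ...) {
  sweep_grid(list(nu_p = nu_p, atot = atot), fixed, list(...), verbose)
}

#' Efficiency landscape over burn rate and substrate concentration
#'
#' Maps the Stokes efficiency over a (`nu_p`, `atot`) grid, optionally for
#' several surface unbinding rates `koff_p` (with `K = koff_p` under the
#' default `kon_p = 1`).  The landscape has an interior optimum; its
#' height falls and its position moves to larger (`nu_p`, `atot`) as the
#' substrate turnover `koff_p` grows.
#'
#' @param nu_p,atot Axis values.
#' @param koff_p One or more surface unbinding rates.
#' @param fixed Non-swept parameters.
#' @param verbose Announce the run count.
#' @param ... Passed to [run_single()].
#' @return A data frame of sweep rows; the per-`koff_p` argmax cells are
#'   attached as attribute `"argmax"`.
#' @export
efficiency_heatmap <- function(nu_p, atot, koff_p = 0.01,
                               fixed = dimensionless_params(),
                               verbose = TRUE, ...) {
  df <- sweep_grid(list(nu_p = nu_p, atot = atot, koff_p = koff_p),
                   fixed, list(...), verbose)
  argmax <- do.call(rbind, lapply(split(df, df$koff_p), function(d) {
    d[which.max(d$eta), c("koff_p", "nu_p", "atot", "eta")]
  }))
  rownames(argmax) <- NULL
  attr(df, "argmax") <- argmax
  df
}

#' Sweep over the complex unbinding rate
#'
#' Steady-state velocity, consumption and efficiency as a function of the
#' zero-force complex dissociation rate `omega_p`, per substrate
#' concentration `atot` and Bell distance `delta`, at fixed burn rate.
#' Within each (`atot`, `delta`) curve the velocity and consumption are
#' also returned normalized by their maxima (`v_norm`, `b_norm`).
#'
#' @param omega_p Unbinding-rate axis (include 0 to anchor the curves).
#' @param atot One or more substrate concentrations.
#' @param delta One or more Bell distances (0 = force-independent
#'   unbinding).
#' @param fixed Non-swept parameters; the burn rate defaults to
#'   `fixed$nu_p = 1`.
#' @param verbose Announce the run count.
#' @param ... Passed to [run_single()].
#' @return A data frame of sweep rows with added `v_norm`, `b_norm`.
#' @export
unbinding_sweep <- function(omega_p, atot = c(1, 10), delta = 0,
                            fixed = dimensionless_params(),
                            verbose = TRUE, ...) {
  df <- sweep_grid(list(omega_p = omega_p, atot = atot, delta = delta),
                   fixed, list(...), verbose)
  key <- interaction(df$atot, df$delta, drop = TRUE)
  df$v_norm <- stats::ave(df$v_ss, key, FUN = normalize_by_max)
  df$b_norm <- stats::ave(df$b_ss, key, FUN = normalize_by_max)
  df
}

#' Reshape sweep rows into a value matrix
#'
#' @param df Sweep-row data frame from [efficiency_heatmap()].
#' @param value Column to tabulate (default `"eta"`).
#' @param path Optional CSV path for the matrix (rows `nu_p`, columns
#'   `atot`).
#' @return A numeric matrix with `nu_p` rows and `atot` columns.
#' @export
heatmap_matrix <- function(df, value = "eta", path = NULL) {
  nu_vals <- sort(unique(df$nu_p))
  at_vals <- sort(unique(df$atot))
  m <- matrix(NA_real_, length(nu_vals), length(at_vals),
              dimnames = list(nu_p = nu_vals, atot = at_vals))
  for (i in seq_len(nrow(df))) {
    m[as.character(df$nu_p[i]), as.character(df$atot[i])] <- df[[value]][i]
  }
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(m), path)
  }
  m
}

#' Plot the velocity and consumption time course of a run
#'
#' @param traj A [integrate_motor()] trajectory.
#' @return A ggplot object with the velocity and consumption traces.
#' @export
plot_velocity_trace <- function(traj) {
  df <- trajectory_table(traj)
  long <- rbind(data.frame(tau = df$tau, value = df$v, series = "velocity v"),
                data.frame(tau = df$tau, value = df$b, series = "consumption b"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(tau), y = NULL)
}

#' Plot an efficiency heatmap
#'
#' @param df Sweep rows from [efficiency_heatmap()].
#' @return A ggplot tile map of efficiency over (`nu_p`, `atot`), one
#'   facet per `koff_p`.
#' @export
plot_efficiency_heatmap <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = factor(signif(.data$nu_p, 3)),
                                   y = factor(signif(.data$atot, 3)),
                                   fill = .data$eta)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~koff_p, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = expression(eta)) +
    ggplot2::labs(x = expression(nu * minute), y = expression(a[tot]))
}
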