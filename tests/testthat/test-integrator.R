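test_that("grids are uniform, counted correctly, and validated", {
  g <- make_grid(-50, 350, 0.1)
  expect_equal(g$n, 4001L)
  expect_true(all(abs(diff(g$x) - 0.1) < 1e-12))
  expect_equal(g$x[1], -50, tolerance = 1e-12)
  expect_equal(g$x[g$n], 350, tolerance = 1e-12)
  expect_error(make_grid(-50, 350, 0), "dx")
  expect_error(make_grid(0, 30, 0.1), "40 sigma")
})

test_that("initial condition is the bulk plateau with a triangular notch", {
  p <- dimensionless_params(atot = 1, koff_p = 0.01)
  g <- make_grid(-30, 30, 0.1)
  plateau <- surface_steady_state(1, p$K)

  st <- initial_condition(g, p, xh0 = 0, well_width = 10,
                          well_depth_fraction = 1)
  expect_true(all(st$a_c == 0))
  expect_equal(st$a_s[g$x > 0 | g$x < -10], rep(plateau, sum(g$x > 0 | g$x < -10)))
  i_min <- which.min(st$a_s)
  expect_equal(g$x[i_min], -5, tolerance = 1e-9)      # notch centre
  expect_equal(min(st$a_s), 0, tolerance = 1e-12)     # full depth

  st2 <- initial_condition(g, p, well_width = 10, well_depth_fraction = 0.4)
  expect_equal(min(st2$a_s), 0.6 * plateau, tolerance = 1e-9)

  st3 <- initial_condition(g, p, well_depth_fraction = 0)
  expect_equal(st3$a_s, rep(plateau, g$n))

  expect_error(initial_condition(g, p, xh0 = -28, well_width = 10), "domain")
  expect_error(initial_condition(g, p, well_depth_fraction = 1.2), "\\[0, 1\\]")
})

test_that("an exactly symmetric state leaves the hub stationary", {
  p <- ref_params()
  g <- make_grid(-30, 30, 0.1)
  st <- initial_condition(g, p, well_depth_fraction = 0)
  traj <- integrate_motor(st, g, p, integration_settings(tau_end = 150))
  expect_true(all(traj$v_t == 0))
  expect_true(all(traj$xh_t == 0))
  ss <- find_steady_state(traj)
  expect_true(ss$stalled)
  expect_gt(ss$b_ss, 0)          # a stalled hub still burns substrate
  expect_equal(ss$eta, 0)
})

test_that("an empty track gives a static hub and zero fields", {
  p <- dimensionless_params(atot = 0, nu_p = 1, koff_p = 0.01)
  g <- make_grid(-30, 30, 0.1)
  st <- initial_condition(g, p, well_depth_fraction = 0)
  traj <- integrate_motor(st, g, p, integration_settings(tau_end = 100))
  expect_true(all(traj$v_t == 0) && all(traj$b_t == 0))
  expect_true(all(traj$final_state$a_s == 0))
})

test_that("near the optimal burn rate the velocity spikes then plateaus", {
  row <- run_single(ref_params(nu_p = 0.42), keep_trajectory = TRUE)
  traj <- attr(row, "trajectory")
  expect_true(row$converged && !row$stalled)
  expect_gt(row$v_ss, 0)
  # the early velocity spike overshoots the eventual steady speed
  expect_gt(max(traj$v_t), row$v_ss)
  expect_lt(which.max(traj$v_t), length(traj$v_t) / 2)
  # consumption plateaus on the same timescale
  expect_equal(traj$b_t[length(traj$b_t)], row$b_ss, tolerance = 5e-3)
  # velocity samples are rhs evaluations, consistent with the position slope
  mid <- seq(50, 100)
  slope <- diff(traj$xh_t[mid]) / diff(traj$times[mid])
  expect_equal(mean(slope), mean(traj$v_t[mid][-1]), tolerance = 1e-2)
})

test_that("the run stops with a flag when the hub nears the domain edge", {
  p <- ref_params()
  g <- make_grid(-30, 25, 0.1)
  st <- initial_condition(g, p)
  traj <- integrate_motor(st, g, p, integration_settings(tau_end = 500))
  expect_true(traj$boundary_hit)
  expect_lt(max(traj$times), 500)
  expect_true(all(traj$xh_t <= 25 - 10 + 1))   # truncated at the margin
})

test_that("shifting the domain and start position shifts only the positions", {
  p <- ref_params()
  s <- integration_settings(tau_end = 80, steady_window = 40)
  g1 <- make_grid(-50, 150, 0.1)
  t1 <- integrate_motor(initial_condition(g1, p), g1, p, s)
  g2 <- make_grid(-30, 170, 0.1)
  t2 <- integrate_motor(initial_condition(g2, p, xh0 = 20), g2, p, s)
  # agreement at the solver-tolerance scale: the two runs take different
  # adaptive step sequences
  expect_equal(t2$xh_t, t1$xh_t + 20, tolerance = 1e-5)
  expect_equal(t2$v_t, t1$v_t, tolerance = 1e-5)
  expect_equal(t2$b_t, t1$b_t, tolerance = 1e-5)
})

synthetic_traj <- function(times, v, b) {
  structure(list(times = times, xh_t = cumsum(c(0, diff(times) * v[-1])),
                 v_t = v, b_t = b, snapshots = list(), final_state = NULL,
                 boundary_hit = FALSE, params = ref_params(),
                 settings = integration_settings(), quadrature = "rectangle"),
            class = "bbr_trajectory")
}

test_that("steady-state extraction classifies plateaus, stalls and decays", {
  tt <- seq(0, 200, by = 1)
  s <- integration_settings()

  const <- synthetic_traj(tt, rep(0.3, length(tt)), rep(0.05, length(tt)))
  ss <- find_steady_state(const, s)
  expect_equal(ss$v_ss, 0.3)
  expect_equal(ss$b_ss, 0.05)
  expect_true(ss$converged && !ss$stalled)
  expect_equal(ss$eta, 0.3^2 / (15 * 0.05))

  decay <- synthetic_traj(tt, 0.5 * exp(-tt / 60), rep(0.05, length(tt)))
  expect_false(find_steady_state(decay, s)$converged)

  stalled <- synthetic_traj(tt, rep(0, length(tt)), rep(0.02, length(tt)))
  ss3 <- find_steady_state(stalled, s)
  expect_true(ss3$stalled && ss3$converged)
  expect_equal(ss3$eta, 0)

  short <- synthetic_traj(seq(0, 40), rep(0.3, 41), rep(0.05, 41))
  expect_error(find_steady_state(short, s), "windows")
})

test_that("trajectory export is tidy and round-trips through CSV", {
  row <- run_single(ref_params(), keep_trajectory = TRUE,
                    settings = integration_settings(tau_end = 100))
  traj <- attr(row, "trajectory")
  f <- withr::local_tempfile(fileext = ".csv")
  df <- trajectory_table(traj, f)
  expect_named(df, c("tau", "xh", "v", "b"))
  expect_true(all(diff(df$tau) > 0))
  back <- utils::read.csv(f)
  expect_equal(back$v, df$v, tolerance = 1e-12)
})
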