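test_that("binding kernel is a unit-peak Gaussian, symmetric about the hub", {
  expect_equal(binding_kernel(3.7, 3.7), 1)
  expect_equal(binding_kernel(1, 0), exp(-0.5))
  x <- seq(-4, 4, by = 0.37)
  xh <- 0.81
  expect_equal(binding_kernel(x, xh), binding_kernel(2 * xh - x, xh))
  expect_true(all(binding_kernel(x, xh) > 0 & binding_kernel(x, xh) <= 1))
})

test_that("hub drift is the first moment of the complex field", {
  g <- make_grid(-20, 20, 0.1)
  # point mass m at xh + d pulls the hub forward with velocity m*d
  a_c <- rep(0, g$n)
  i <- which.min(abs(g$x - 3))          # node at x = 3
  a_c[i] <- 2 / g$dx                    # total mass 2
  expect_equal(hub_drift(a_c, g, 0), 2 * g$x[i], tolerance = 1e-12)
  # equal masses ahead and behind cancel
  j <- which.min(abs(g$x + 3))
  a_c[j] <- a_c[i]
  expect_equal(hub_drift(a_c, g, 0), 0, tolerance = 1e-12)
  # a field symmetric about the hub produces no drift
  sym <- binding_kernel(g$x, 0)
  expect_equal(hub_drift(sym, g, 0), 0, tolerance = 1e-13)
  expect_error(hub_drift(c(a_c[-1], NaN), g, 0), "non-finite")
})

test_that("replenishment source balances surface turnover", {
  expect_equal(replenishment_rate(dimensionless_params(koff_p = 0)), 0)
  p <- dimensionless_params(atot = 1, koff_p = 0.01, kon_p = 1e9)  # K ~ 0
  expect_equal(replenishment_rate(p), 0.01, tolerance = 1e-9)
  p2 <- dimensionless_params(atot = 1, koff_p = 0.01)              # K = 0.01
  expect_equal(replenishment_rate(p2), 0.01 / 1.01)
})

test_that("bulk surface steady state partitions substrate by turnover", {
  expect_equal(surface_steady_state(3, 0), 3)
  expect_equal(surface_steady_state(1, 1), 0.5)
  expect_equal(surface_steady_state(1, 0.01), 1 / 1.01)
})

test_that("rhs vanishes on an empty closed system and at the bulk steady state", {
  g <- make_grid(-25, 25, 0.1)
  p <- dimensionless_params(atot = 1, nu_p = 1, koff_p = 0)
  d <- rhs(field_state(0, rep(0, g$n), rep(0, g$n), g), g, p)
  expect_equal(d$dxh, 0)
  expect_true(all(d$da_s == 0) && all(d$da_c == 0))

  # uniform surface field at atot/(1+K): source and turnover loss cancel
  # exactly away from the hub (binding loss < e^-50 beyond 10 sigma)
  p2 <- dimensionless_params(atot = 1, koff_p = 0.01)
  as0 <- rep(surface_steady_state(1, p2$K), g$n)
  d2 <- rhs(field_state(0, as0, rep(0, g$n), g), g, p2)
  far <- abs(g$x) >= 10
  expect_true(all(abs(d2$da_s[far]) < 1e-20))
})

test_that("delta only enters the rhs through the omega' term", {
  g <- make_grid(-25, 25, 0.1)
  st <- random_state(g, 11)
  p0 <- dimensionless_params(omega_p = 0, delta = 0)
  p1 <- dimensionless_params(omega_p = 0, delta = 2)
  expect_identical(rhs(st, g, p0), rhs(st, g, p1))
})

test_that("omega' exchange moves complex to surface node by node", {
  g <- make_grid(-25, 25, 0.1)
  st <- random_state(g, 21)
  p_off <- dimensionless_params(atot = 1, nu_p = 0.7, omega_p = 0)
  p_on <- dimensionless_params(atot = 1, nu_p = 0.7, omega_p = 0.3,
                               delta = 0.5)
  d_off <- rhs(st, g, p_off)
  d_on <- rhs(st, g, p_on)
  removed <- d_off$da_c - d_on$da_c    # omega' term removed from complex
  added <- d_on$da_s - d_off$da_s      # omega' term added to surface
  expect_equal(removed, added, tolerance = 1e-14)
  expect_true(all(removed[st$a_c > 0] > 0))
})

test_that("rhs preserves nonnegativity at the boundary of the state space", {
  g <- make_grid(-25, 25, 0.5)
  p <- dimensionless_params(atot = 1, nu_p = 2, koff_p = 0.01,
                            omega_p = 0.2, delta = 0.3)
  for (seed in 1:5) {
    st <- random_state(g, seed)
    zero_c <- sample(g$n, 10)
    zero_s <- sample(g$n, 10)
    st$a_c[zero_c] <- 0
    st$a_s[zero_s] <- 0
    d <- rhs(st, g, p)
    expect_true(all(d$da_c[zero_c] >= 0))
    expect_true(all(d$da_s[zero_s] > 0))   # source is strictly positive
  }
})

test_that("rhs is invariant under whole-cell translations", {
  g <- make_grid(-25, 25, 0.1)
  p <- dimensionless_params(atot = 1, nu_p = 1, omega_p = 0.1, delta = 0.4)
  st <- random_state(g, 31, xh = 0.73)
  k <- 40                                        # shift by 4 sigma
  g2 <- make_grid(-25 + k * g$dx, 25 + k * g$dx, g$dx)
  st2 <- field_state(st$xh + k * g$dx, st$a_s, st$a_c, g2)
  d1 <- rhs(st, g, p)
  d2 <- rhs(st2, g2, p)
  expect_equal(d1$dxh, d2$dxh, tolerance = 1e-10)
  expect_equal(d1$da_s, d2$da_s, tolerance = 1e-10)
  expect_equal(d1$da_c, d2$da_c, tolerance = 1e-10)
})

test_that("stalled consumption oracle is nu'-free and falls with turnover", {
  p <- dimensionless_params(atot = 1, koff_p = 0.01)
  b1 <- stalled_consumption_oracle(p)
  b2 <- stalled_consumption_oracle(dimensionless_params(atot = 1,
                                                        koff_p = 0.01,
                                                        nu_p = 17))
  expect_identical(b1, b2)
  # the per-substrate capture efficiency (integral factor) decreases
  # monotonically with koff' at fixed K
  K <- 0.01
  fac <- vapply(c(0.001, 0.01, 0.1, 1), function(k) {
    pk <- dimensionless_params(atot = 1, koff_p = k, kon_p = k / K)
    stalled_consumption_oracle(pk) / replenishment_rate(pk)
  }, numeric(1))
  expect_true(all(diff(fac) < 0))
  expect_error(stalled_consumption_oracle(dimensionless_params(omega_p = 1)),
               "omega")
  expect_error(stalled_consumption_oracle(dimensionless_params(koff_p = 0)),
               "koff")
})

test_that("compiled and reference rhs produce the same trajectories", {
  # dual route: integrate a short horizon with the compiled derivative and
  # with the plain-R rhs() through the same solver, including the Bell term
  g <- make_grid(-20, 20, 0.2)
  p <- dimensionless_params(atot = 1, nu_p = 1, koff_p = 0.01,
                            omega_p = 0.5, delta = 0.5)
  st <- initial_condition(g, p, xh0 = 0, well_width = 6)
  y0 <- c(st$xh, st$a_s, st$a_c)
  tt <- seq(0, 5, by = 0.5)
  n <- g$n
  r_func <- function(t, y, parms) {
    s <- list(xh = y[1], a_s = y[2:(n + 1)], a_c = y[(n + 2):(2 * n + 1)])
    d <- rhs(s, g, p)
    list(c(d$dxh, d$da_s, d$da_c))
  }
  sol_r <- deSolve::ode(y0, tt, r_func, parms = NULL, method = "ode45",
                        rtol = 1e-9, atol = 1e-12)
  sol_c <- deSolve::ode(y0, tt, func = "bbr_derivs",
                        parms = bbrmotor:::bbr_parms(g, p, "rectangle"),
                        dllname = "bbrmotor", initfunc = "bbr_initmod",
                        nout = 2, outnames = c("v", "b"), method = "ode45",
                        rtol = 1e-9, atol = 1e-12)
  expect_equal(unname(sol_r[, 2]), unname(sol_c[, 2]), tolerance = 1e-8)
  expect_lt(max(abs(sol_r[, 3:(2 * n + 2)] - sol_c[, 3:(2 * n + 2)])), 1e-8)
})
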