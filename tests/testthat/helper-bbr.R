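# shared fixtures for the test suite; everything is generated in code

# reference parameter set used throughout: atot = 1, nu' = 1,
# koff' = K = 0.01, omega' = 0, dg = 15
ref_params <- function(...) {
  args <- list(atot = 1, nu_p = 1, koff_p = 0.01)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(dimensionless_params, args)
}

# settings for symmetric (stalled) runs: the surface field relaxes on the
# slow turnover timescale 1/koff' = 100 tau, so the run needs a long
# horizon and tight solver tolerances to pin the consumption rate
stall_settings <- function(tau_end = 800) {
  integration_settings(tau_end = tau_end, rel_tol = 1e-8, abs_tol = 1e-11,
                       steady_rel_tol = 1e-6)
}

# symmetric stalled steady-state run (uniform surface field, no well);
# domain symmetric about the hub so the zero-force state is preserved
run_stalled <- function(params, tau_end = 800) {
  run_single(params, settings = stall_settings(tau_end),
             well_depth_fraction = 0, domain_behind = 30, domain_ahead = 30)
}

# deterministic pseudo-random field state for property tests
random_state <- function(grid, seed, xh = 0) {
  set.seed(seed)
  field_state(xh, stats::runif(grid$n, 0, 2), stats::runif(grid$n, 0, 1),
              grid)
}
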