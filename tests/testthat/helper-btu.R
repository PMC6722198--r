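# Shared fixtures: everything is generated in code, no stored data.

# reduced-size parameter sets for fast solver tests; the default regime is
# well mixed (diffusion time << exchange time), so centre-point behaviour
# is grid-insensitive and small grids are representative
small_params <- function(nx = 11L) default_params(nx = nx, ny = nx)

# equilibrium initial state for a given uniform free concentration
equilibrium_init <- function(dp, C0) {
  list(C = C0,
       B1 = if (dp$B1max > 0) equilibrium_bound(C0, dp$B1max, dp$k1on, dp$k1off) else 0,
       B2 = if (dp$B2max > 0) equilibrium_bound(C0, dp$B2max, dp$k2on, dp$k2off) else 0)
}

# coarse default-parameter run cached across tests in one file
run_cache <- local({
  cache <- list()
  function(key, fn) {
    if (is.null(cache[[key]])) cache[[key]] <<- fn()
    cache[[key]]
  }
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
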