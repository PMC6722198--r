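# Solver tests run on reduced grids: the default regime is well mixed
# (diffusion time 50 s << exchange time 1.25e4 s), so centre-point series
# are grid-insensitive; spatial structure tests use the snapshot fields.

test_that("impermeable walls and zero initial state stay exactly zero", {
  p <- small_params(9L)
  dp0 <- modify_drug(p$drug, P = 0)
  res <- simulate_unit(dp0, p$dosing, p$domain, t_end = 1e4,
                       output_times = c(0, 1e3, 1e4))
  expect_equal(max(abs(res$center$C)), 0)
  expect_equal(max(abs(res$content)), 0)
})

test_that("constant forcing without binding matches the well-mixed closed form", {
  p <- small_params(11L)
  dp <- modify_drug(p$drug, B1max = 0, B2max = 0)
  k_ex <- 2 * dp$P * (p$domain$xr + p$domain$yr) / (p$domain$xr * p$domain$yr)
  cbar <- 1
  t_end <- 4e4
  res <- simulate_unit(dp, p$dosing, p$domain, t_end = t_end,
                       cpl_fun = function(t) cbar)
  sel <- res$times > 500   # skip the diffusion boundary-layer transient
  exact <- cbar * (1 - exp(-k_ex * res$times[sel]))
  expect_rel_equal(res$center$C[sel], exact, 0.01)
})

test_that("v = 0 solutions are mirror symmetric; advection breaks x only", {
  p <- small_params(11L)
  dp0 <- modify_drug(p$drug, v = 0)
  res <- simulate_unit(dp0, p$dosing, p$domain, t_end = 2e4,
                       snapshot_times = c(1e3, 2e4))
  for (s in res$snapshots) {
    e <- symmetry_error(s)
    expect_lt(max(e), 1e-8)
  }
  # strong advection case: x asymmetry dominates y asymmetry early on
  dpv <- modify_drug(p$drug, v = 5e-6, D_eff = 5e-12, P = 1e-7)
  resv <- simulate_unit(dpv, p$dosing, p$domain, t_end = 500,
                        snapshot_times = 250)
  ev <- symmetry_error(resv$snapshots[[1]])
  expect_gt(ev["x"], ev["y"])
  expect_lt(ev["y"], 1e-8)
})

test_that("positivity and binding caps hold over a full default run", {
  p <- small_params(11L)
  res <- run_cache("default11", function()
    simulate_unit(p$drug, p$dosing, p$domain, t_end = 2e5,
                  snapshot_times = c(1e2, 1e3, 1e4, 1e5)))
  expect_gt(min(res$center$C, res$center$B1, res$center$B2), -1e-9)
  expect_lt(max(res$center$B1), p$drug$B1max * (1 + 1e-9))
  expect_lt(max(res$center$B2), p$drug$B2max * (1 + 1e-9))
  for (s in res$snapshots) {
    expect_gt(min(s$C, s$B1, s$B2), -1e-9)
    expect_lt(max(s$B1), p$drug$B1max * (1 + 1e-9))
  }
  # saturable vs non-saturable regimes: B1 approaches its cap, B2 stays far
  # below (dense weak sites)
  expect_gt(max(res$center$B1) / p$drug$B1max, 0.9)
  expect_lt(max(res$center$B2) / p$drug$B2max, 0.01)
})

test_that("identical inputs give identical outputs (determinism)", {
  p <- small_params(7L)
  r1 <- simulate_unit(p$drug, p$dosing, p$domain, t_end = 5e3)
  r2 <- simulate_unit(p$drug, p$dosing, p$domain, t_end = 5e3)
  expect_identical(r1$center, r2$center)
  expect_identical(r1$content, r2$content)
})

test_that("early-time uptake is advection-shifted towards the left wall", {
  sm <- run_spatial_maps(nx = 15L, snapshot_times = c(250, 5000))
  s <- sm$result$snapshots[[1]]
  nx <- 15L
  left <- mean(s$C[seq_len(nx) <= nx / 2, ])
  right <- mean(s$C[seq_len(nx) > (nx + 1) / 2, ])
  expect_gt(left / right, 1)
})

test_that("dimensionless groups report the canonical scales", {
  p <- default_params()
  g <- nondimensionalize(p$drug, p$dosing, p$domain)
  expect_equal(g$peclet, 0.5)
  expect_equal(g$t_diff, 50)
  expect_equal(g$k_ex, 8e-5)
  expect_equal(g$t_exchange, 1.25e4)
  expect_equal(g$biot, 1e-3)
  expect_equal(g$xhat(p$domain$xr), 1)
  expect_equal(g$that(p$domain$xr^2 / p$drug$D_eff), 1)
})

test_that("solver failure carries the last successful time", {
  p <- small_params(5L)
  # forcing that blows up mid-run makes the integrator stall and report
  bad_cpl <- function(t) if (t < 100) 1 else NaN
  expect_error(
    simulate_unit(p$drug, p$dosing, p$domain, t_end = 1e3,
                  output_times = c(0, 1e3), cpl_fun = bad_cpl),
    "last successful time")
})
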