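test_that("well-mixed reduction reproduces closed forms before use as oracle", {
  p <- default_params()
  dp <- modify_drug(p$drug, B1max = 0, B2max = 0)
  k_ex <- 2 * dp$P * (p$domain$xr + p$domain$yr) / (p$domain$xr * p$domain$yr)
  expect_equal(k_ex, 8e-5)   # 4P/L for the square unit
  # no binding, constant forcing: C(t) = cbar (1 - exp(-k_ex t))
  ts <- c(0, 100, 1e3, 1e4, 1e5)
  wm <- simulate_well_mixed(dp, p$dosing, p$domain, t_end = 1e5,
                            output_times = ts, cpl_fun = function(t) 2,
                            opts = solver_options(rtol = 1e-9, atol = 1e-15))
  expect_rel_equal(wm$C[-1], 2 * (1 - exp(-k_ex * ts[-1])), 1e-6)
  expect_equal(wm$B1, rep(0, 5))
  # P = 0: identically zero from the zero state
  wm0 <- simulate_well_mixed(modify_drug(p$drug, P = 0), p$dosing,
                             p$domain, t_end = 1e4, output_times = c(0, 1e4))
  expect_equal(max(abs(wm0$C)), 0)
})

test_that("oracle gap shrinks as diffusion gets faster", {
  p <- small_params(11L)
  t_end <- 2e4
  gaps <- vapply(c(1, 10, 100), function(m) {
    dp <- modify_drug(p$drug, D_eff = p$drug$D_eff * m)
    res <- simulate_unit(dp, p$dosing, p$domain, t_end = t_end)
    wm <- simulate_well_mixed(dp, p$dosing, p$domain, t_end = t_end)
    oracle_gap(res, wm)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
})

test_that("oracle gap validates inputs", {
  p <- small_params(7L)
  res <- simulate_unit(p$drug, p$dosing, p$domain, t_end = 1e3,
                       output_times = c(0, 500, 1e3))
  wm <- simulate_well_mixed(p$drug, p$dosing, p$domain, t_end = 1e3,
                            output_times = c(0, 600, 1e3))
  expect_error(oracle_gap(res, wm), "time grids")
  res_short <- simulate_unit(p$drug, p$dosing, p$domain, t_end = 400,
                             output_times = c(0, 100, 400))
  wm_short <- simulate_well_mixed(p$drug, p$dosing, p$domain, t_end = 400,
                                  output_times = c(0, 100, 400))
  expect_error(oracle_gap(res_short, wm_short), "burn-in")  # all t <= 10 t_diff
})

test_that("mass-balance audit closes on open, closed and refined runs", {
  p <- small_params(11L)
  st <- c(0, 10^seq(1, log10(2e5), length.out = 40))
  res <- run_cache("mb11", function()
    simulate_unit(p$drug, p$dosing, p$domain, t_end = 2e5,
                  snapshot_times = st))
  mb <- mass_balance_residual(res)
  expect_lt(attr(mb, "max_rel"), 1e-3)
  # the advective through-flux is a real but small part of the budget
  i_pk <- which.max(abs(mb$influx_bbb))
  expect_lt(abs(mb$influx_advective[i_pk] / mb$influx_bbb[i_pk]), 0.05)
  # integrator-accumulated audit is tighter still
  expect_lt(res$diagnostics$mass_balance_rel, 1e-6)
  # closed domain from an equilibrium state: conserved to solver precision
  dp0 <- modify_drug(p$drug, P = 0)
  res0 <- simulate_unit(dp0, p$dosing, p$domain, t_end = 1e4,
                        snapshot_times = c(0, 1e3, 5e3, 1e4),
                        init = equilibrium_init(dp0, 1))
  expect_lt(max(abs(res0$content - res0$content[1])) / res0$content[1], 1e-6)
  mb0 <- mass_balance_residual(res0)
  expect_lt(attr(mb0, "max_rel"), 1e-6)
  # audit stays closed under grid refinement
  p2 <- small_params(21L)
  res2 <- simulate_unit(p2$drug, p2$dosing, p2$domain, t_end = 2e5,
                        snapshot_times = st)
  expect_lt(attr(mass_balance_residual(res2), "max_rel"), 1e-3)
  expect_error(mass_balance_residual(
    simulate_unit(p$drug, p$dosing, p$domain, 1e3,
                  snapshot_times = c(0, 1e3))), "3 snapshots")
})

test_that("symmetry error: trivial cases and validation", {
  f <- structure(list(t = 0, C = matrix(3.2, 5, 5)), class = "btu_state")
  expect_equal(symmetry_error(f), c(x = 0, y = 0))
  z <- structure(list(t = 0, C = matrix(0, 5, 5)), class = "btu_state")
  expect_equal(symmetry_error(z), c(x = 0, y = 0))
  g <- structure(list(t = 0, C = matrix(seq_len(20) / 20, 4, 5)),
                 class = "btu_state")
  expect_error(symmetry_error(g), "square")
  expect_error(symmetry_error(f, "B9"), "B9")
})
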