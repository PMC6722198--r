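test_that("default parameter preset matches the canonical table field-for-field", {
  p <- default_params()
  expect_equal(p$drug$D_eff, 5e-11)
  expect_equal(p$drug$v, 5e-7)
  expect_equal(p$drug$P, 1e-9)
  expect_equal(p$drug$B1max, 5e-2)
  expect_equal(p$drug$k1on, 1)
  expect_equal(p$drug$k1off, 1e-2)
  expect_equal(p$drug$B2max, 50)
  expect_equal(p$drug$k2on, 1e-2)
  expect_equal(p$drug$k2off, 1)
  expect_equal(p$dosing$route, "oral")
  expect_equal(p$dosing$F_bio, 1)
  expect_equal(p$dosing$Dose, 30)
  expect_equal(p$dosing$ka, 2e-4)
  expect_equal(p$dosing$ke, 5e-5)
  expect_equal(p$dosing$V, 20)
  expect_equal(p$domain$xr, 5e-5)
  expect_equal(p$domain$yr, 5e-5)
  # provenance relations of the assumed non-specific constants
  expect_equal(p$drug$k2on, p$drug$k1on / 100)
  expect_equal(p$drug$k2off, p$drug$k1off * 100)
  expect_equal(p$drug$B2max, p$drug$B1max * 1000)
})

test_that("spatial-experiment preset overrides exactly the stated fields", {
  p <- spatial_experiment_params()
  d <- default_params()
  expect_equal(p$drug$D_eff, 5e-12)
  expect_equal(p$drug$P, 1e-7)
  expect_equal(p$drug$k1on, 10)
  expect_equal(p$drug$B1max, 1e-1)
  expect_equal(p$drug$B2max, 100)
  expect_equal(p$dosing$Dose, 100)
  # all non-overridden fields equal the defaults
  for (nm in c("v", "k1off", "k2on", "k2off"))
    expect_equal(p$drug[[nm]], d$drug[[nm]], info = nm)
  for (nm in c("route", "F_bio", "ka", "ke", "V"))
    expect_equal(p$dosing[[nm]], d$dosing[[nm]], info = nm)
  expect_equal(unclass(p$domain), unclass(d$domain))
})

test_that("parameter constructors reject invalid values", {
  p <- default_params()
  expect_error(modify_drug(p$drug, P = -1), "P")
  expect_error(modify_drug(p$drug, B1max = Inf), "finite")
  expect_error(modify_dosing(p$dosing, F_bio = 1.5), "0, 1")
  expect_error(modify_dosing(p$dosing, V = 0), "V")
  expect_error(domain2d(nx = 2), "nx")
  expect_error(domain2d(xr = 0), "xr")
})

test_that("range validation reports per-parameter status and only warns", {
  p <- default_params()
  rep <- suppressWarnings(validate_params(p$drug, p$dosing))
  expect_s3_class(rep, "data.frame")
  get <- function(nm, col) rep[[col]][rep$param == nm]
  # no literature ranges exist for the non-specific binding constants
  for (nm in c("k2on", "k2off", "B2max"))
    expect_equal(get(nm, "status"), "unchecked", info = nm)
  # the elimination-rate range row is stored as printed and flagged
  expect_true(get("ke", "flagged"))
  expect_equal(get("ke", "status"), "out-of-range")
  # everything else in the default set is inside its range
  checked <- setdiff(rep$param[rep$status != "unchecked"], "ke")
  expect_true(all(rep$status[rep$param %in% checked] == "in-range"))
  # out-of-range warns, never errors
  expect_warning(validate_params(modify_drug(p$drug, P = 1), p$dosing), "P")
  rep2 <- validate_params(modify_drug(p$drug, P = 1), p$dosing, warn = FALSE)
  expect_equal(rep2$status[rep2$param == "P"], "out-of-range")
  # idempotent / side-effect free
  expect_identical(suppressWarnings(validate_params(p$drug, p$dosing)), rep)
})

test_that("range table stores the printed inconsistent row verbatim", {
  rt <- physiological_ranges()
  ke <- rt[rt$param == "ke", ]
  expect_equal(ke$low, 1e-1)
  expect_equal(ke$high, 5e-3)
  expect_true(ke$inconsistent)
  expect_true(all(rt$low[!rt$inconsistent] <= rt$high[!rt$inconsistent]))
})

test_that("tortuosity relation D* = D / lambda^2", {
  expect_equal(tortuosity_to_Deff(3e-10, 1), 3e-10)
  expect_equal(tortuosity_to_Deff(1e-10, 2), 2.5e-11)
  # round trip: lambda = sqrt(D / D*)
  D <- 7.3e-10; lam <- 1.6
  expect_equal(sqrt(D / tortuosity_to_Deff(D, lam)), lam)
  # strictly decreasing in lambda
  lams <- c(1, 1.3, 1.7, 2.5, 4)
  expect_true(all(diff(tortuosity_to_Deff(1e-10, lams)) < 0))
  expect_error(tortuosity_to_Deff(1e-10, 0), "lam")
  expect_error(tortuosity_to_Deff(0, 1), "D")
})
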