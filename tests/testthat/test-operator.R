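test_that("3x3 operator matches a hand-assembled stencil", {
  # deliberately asymmetric spacing and plain numbers so every entry can be
  # recomputed by hand: hx = 1/2, hy = 1/4 (xr = 1, yr = 0.5)
  dp <- drug_params(D_eff = 2, v = 3, P = 5, k1on = 0, k1off = 0,
                    B1max = 0, k2on = 0, k2off = 0, B2max = 0)
  dom <- domain2d(xr = 1, yr = 0.5, nx = 3L, ny = 3L)
  op <- assemble_transport(dp, dom, "central")
  A <- as.matrix(op$A)
  hx <- 0.5; hy <- 0.25; D <- 2; v <- 3; P <- 5
  # centre node k = 5, neighbours 4 (left), 6 (right), 2 (down), 8 (up)
  expect_equal(A[5, 4], D / hx^2 + v / (2 * hx))
  expect_equal(A[5, 6], D / hx^2 - v / (2 * hx))
  expect_equal(A[5, 2], D / hy^2)
  expect_equal(A[5, 8], D / hy^2)
  expect_equal(A[5, 5], -2 * D / hx^2 - 2 * D / hy^2)
  expect_equal(op$w[5], 0)
  # mid-left wall node k = 4 (i=1, j=2): x-ghost elimination plus Robin
  # advection derivative; y part is interior
  expect_equal(A[4, 5], 2 * D / hx^2)                      # reflected x-neighbour
  expect_equal(A[4, 1], D / hy^2)
  expect_equal(A[4, 7], D / hy^2)
  expect_equal(A[4, 4], -2 * D / hx^2 - 2 * P / hx - 2 * D / hy^2 - v * P / D)
  expect_equal(op$w[4], 2 * P / hx + v * P / D)
  # corner node k = 1 (i=1, j=1): Robin closure on both incident walls
  expect_equal(A[1, 2], 2 * D / hx^2)
  expect_equal(A[1, 4], 2 * D / hy^2)
  expect_equal(A[1, 1], -2 * D / hx^2 - 2 * P / hx - 2 * D / hy^2 -
                 2 * P / hy - v * P / D)
  expect_equal(op$w[1], 2 * P / hx + 2 * P / hy + v * P / D)
  # right wall (i=3, j=2), k = 6: outflow advection closure has opposite sign
  expect_equal(A[6, 6], -2 * D / hx^2 - 2 * P / hx - 2 * D / hy^2 + v * P / D)
  expect_equal(op$w[6], 2 * P / hx - v * P / D)
})

test_that("upwind scheme differences one-sided against the flow", {
  dp <- drug_params(D_eff = 2, v = 3, P = 5, k1on = 0, k1off = 0,
                    B1max = 0, k2on = 0, k2off = 0, B2max = 0)
  dom <- domain2d(xr = 1, yr = 0.5, nx = 3L, ny = 3L)
  op <- assemble_transport(dp, dom, "upwind")
  A <- as.matrix(op$A)
  hx <- 0.5; D <- 2; v <- 3
  expect_equal(A[5, 4], D / hx^2 + v / hx)
  expect_equal(A[5, 6], D / hx^2)            # no downstream advection coupling
  expect_equal(A[5, 5], -2 * D / hx^2 - 2 * D / 0.25^2 - v / hx)
})

test_that("uniform equilibrium states are discrete steady states", {
  p <- small_params(7L)
  dom <- p$domain
  # closed domain (P = 0), uniform C, bound pools at equilibrium: RHS = 0
  dp0 <- modify_drug(p$drug, P = 0)
  ini <- equilibrium_init(dp0, 0.8)
  r <- semidiscrete_rhs(1e3, matrix(ini$C, 7, 7), matrix(ini$B1, 7, 7),
                        matrix(ini$B2, 7, 7), dp0, p$dosing, dom)
  expect_lt(max(abs(unlist(r))), 1e-15)
  # open domain with C = Cpl(t): boundary terms vanish too
  t0 <- 5e3
  cplv <- cpl(t0, p$dosing)
  ini <- equilibrium_init(p$drug, cplv)
  r2 <- semidiscrete_rhs(t0, matrix(ini$C, 7, 7), matrix(ini$B1, 7, 7),
                         matrix(ini$B2, 7, 7), p$drug, p$dosing, dom)
  expect_lt(max(abs(unlist(r2))), 1e-12)
  # non-finite state is rejected with a time stamp
  bad <- matrix(ini$C, 7, 7); bad[3, 3] <- NaN
  expect_error(semidiscrete_rhs(t0, bad, matrix(0, 7, 7), matrix(0, 7, 7),
                                p$drug, p$dosing, dom), "non-finite")
})

test_that("trapezoidal weights and wall flux close the discrete balance", {
  p <- small_params(9L)
  dp <- p$drug; dom <- p$domain
  op <- assemble_transport(dp, dom)
  qw <- btu2d:::quad_weights(dom)
  u <- btu2d:::wall_flux_weights(dp, dom)
  ac <- btu2d:::advective_flux_coefs(dp, dom, "central")
  aw <- as.numeric(qw$area)
  expect_equal(sum(aw), dom$xr * dom$yr)
  expect_equal(sum(u), dp$P * 2 * (dom$xr + dom$yr))
  # summation by parts: weighted divergence = BBB flux + advective wall term,
  # exactly, for arbitrary fields
  set.seed(7)
  for (rep in 1:5) {
    C <- runif(81); cplv <- runif(1, 0, 2)
    lhs <- sum(aw * (as.numeric(op$A %*% C) + cplv * op$w))
    rhs <- cplv * sum(u) - sum(u * C) + sum(ac$vec * C) + ac$cpl_coef * cplv
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # advective term vanishes for v = 0 and for x-symmetric fields
  ac0 <- btu2d:::advective_flux_coefs(modify_drug(dp, v = 0), dom)
  expect_equal(ac0$vec, rep(0, 81))
  Csym <- as.numeric(outer(abs(seq(-1, 1, length.out = 9)), runif(9)))
  expect_lt(abs(sum(ac$vec * Csym)), 1e-18)
})
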