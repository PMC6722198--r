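# Spatial discretisation of the brain tissue unit: node-centered uniform
# grid with boundary nodes exactly on the capillary walls. Second-order
# central finite differences; the Robin (flux-matching) wall condition
#   inward diffusive flux = P (Cpl(t) - C_wall)   on all four walls
# is imposed by ghost-node elimination, so the transport part of dC/dt is
# affine in C:  A C + Cpl(t) * w.  Corner nodes receive the closure on both
# incident walls. Advection acts in +x only; at the x-walls the wall-normal
# derivative needed by the advection term comes from the same Robin relation
# (dC/dx = -(P/D*)(Cpl - C) at x = 0, +(P/D*)(Cpl - C) at x = xr).

#' Node coordinates of a domain grid
#'
#' @param dom A [domain2d()] object.
#' @return List with vectors `x` (length nx), `y` (length ny), and matrices
#'   `X`, `Y` (nx x ny) of node coordinates in metres; `(0,0)` is the
#'   lower-left corner.
#' @export
grid_coords <- function(dom) {
  x <- seq(0, dom$xr, length.out = dom$nx)
  y <- seq(0, dom$yr, length.out = dom$ny)
  list(x = x, y = y,
       X = matrix(x, dom$nx, dom$ny),
       Y = matrix(y, dom$nx, dom$ny, byrow = TRUE))
}

# Trapezoidal quadrature weights over the area (interior 1, edges 1/2,
# corners 1/4, times hx*hy) and along each wall, matching the node-centered
# grid at second order.
quad_weights <- function(dom) {
  wx <- rep(1, dom$nx); wx[c(1, dom$nx)] <- 0.5
  wy <- rep(1, dom$ny); wy[c(1, dom$ny)] <- 0.5
  area <- outer(wx, wy) * dom$hx * dom$hy
  wall_x <- wx * dom$hx   # along a horizontal wall (y = 0 or yr)
  wall_y <- wy * dom$hy   # along a vertical wall (x = 0 or xr)
  list(area = area, wall_x = wall_x, wall_y = wall_y)
}

#' Assemble the discrete transport operator
#'
#' Builds the sparse matrix `A` and forcing vector `w` such that the
#' semidiscrete transport contribution to the free-drug field (stacked
#' column-major, x fastest) is `A C + Cpl(t) w`.
#'
#' @param dp A [drug_params()] object (uses `D_eff`, `v`, `P`).
#' @param dom A [domain2d()] object.
#' @param advection_scheme `"central"` (second order; default) or
#'   `"upwind"` (first order, for robustness sweeps; requires `v >= 0`).
#' @return List with sparse `A` (dgCMatrix, n x n with n = nx*ny), numeric
#'   `w` (length n), and the `dom` used.
#' @export
assemble_transport <- function(dp, dom, advection_scheme = c("central", "upwind")) {
  advection_scheme <- match.arg(advection_scheme)
  nx <- dom$nx; ny <- dom$ny; n <- nx * ny
  hx <- dom$hx; hy <- dom$hy
  D <- dp$D_eff; v <- dp$v; P <- dp$P
  if (v < 0) stop("assemble_transport: bulk flow v must be >= 0 (+x direction)")
  idx <- function(i, j) i + (j - 1L) * nx

  cap <- 9L * n
  ii <- integer(cap); jj <- integer(cap); xx <- numeric(cap)
  ptr <- 0L
  w <- numeric(n)
  add <- function(i, j, val) {
    ptr <<- ptr + 1L
    ii[ptr] <<- i; jj[ptr] <<- j; xx[ptr] <<- val
  }

  # per-node assembly mirrors the stencil; grids here are small (<= ~2600
  # nodes) so the explicit double loop stays cheap.
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- idx(i, j)
      # --- diffusion, x direction ---
      if (i > 1L && i < nx) {
        add(k, idx(i - 1L, j), D / hx^2)
        add(k, k, -2 * D / hx^2)
        add(k, idx(i + 1L, j), D / hx^2)
      } else {
        kn <- if (i == 1L) idx(2L, j) else idx(nx - 1L, j)
        add(k, kn, 2 * D / hx^2)
        add(k, k, -2 * D / hx^2 - 2 * P / hx)
        w[k] <- w[k] + 2 * P / hx
      }
      # --- diffusion, y direction ---
      if (j > 1L && j < ny) {
        add(k, idx(i, j - 1L), D / hy^2)
        add(k, k, -2 * D / hy^2)
        add(k, idx(i, j + 1L), D / hy^2)
      } else {
        kn <- if (j == 1L) idx(i, 2L) else idx(i, ny - 1L)
        add(k, kn, 2 * D / hy^2)
        add(k, k, -2 * D / hy^2 - 2 * P / hy)
        w[k] <- w[k] + 2 * P / hy
      }
      # --- advection, -v dC/dx ---
      if (v > 0) {
        if (i == 1L) {
          # Robin wall: dC/dx = -(P/D)(Cpl - C) at x = 0
          add(k, k, -v * P / D)
          w[k] <- w[k] + v * P / D
        } else if (i == nx) {
          if (advection_scheme == "central") {
            # dC/dx = +(P/D)(Cpl - C) at x = xr
            add(k, k, v * P / D)
            w[k] <- w[k] - v * P / D
          } else {
            add(k, idx(nx - 1L, j), v / hx)
            add(k, k, -v / hx)
          }
        } else if (advection_scheme == "central") {
          add(k, idx(i - 1L, j), v / (2 * hx))
          add(k, idx(i + 1L, j), -v / (2 * hx))
        } else {
          add(k, idx(i - 1L, j), v / hx)
          add(k, k, -v / hx)
        }
      }
    }
  }
  A <- Matrix::sparseMatrix(i = ii[seq_len(ptr)], j = jj[seq_len(ptr)],
                            x = xx[seq_len(ptr)], dims = c(n, n),
                            repr = "C")
  list(A = A, w = w, dom = dom)
}

# Exact advective boundary flux of the discrete scheme, by summation by
# parts: the trapezoidal-weighted sum of the advection stencil over the
# domain telescopes to a wall term, returned here as coefficients such that
#   net advective influx = sum(vec * C) + cpl_coef * Cpl(t).
# For the central scheme (per row j, weight Wj = hy * wy_j):
#   v*Wj*[ (hx P/(2D))(C[nx,j]-C[1,j]) + (C[1,j]+C[2,j]-C[nx,j]-C[nx-1,j])/2 ]
# and for upwind:
#   v*Wj*[ (hx P/(2D))(Cpl-C[1,j]) + C[1,j] - C[nx-1,j]/2 - C[nx,j]/2 ].
# This term is genuine model physics (bulk flow carries drug through the
# unit); it vanishes for v = 0 or a left-right symmetric field.
advective_flux_coefs <- function(dp, dom, advection_scheme = "central") {
  nx <- dom$nx; ny <- dom$ny; n <- nx * ny
  vec <- numeric(n); cpl_coef <- 0
  v <- dp$v
  if (v == 0) return(list(vec = vec, cpl_coef = 0))
  hx <- dom$hx; hy <- dom$hy
  r <- hx * dp$P / (2 * dp$D_eff)
  wy <- rep(1, ny); wy[c(1, ny)] <- 0.5
  idx <- function(i, j) i + (j - 1L) * nx
  for (j in seq_len(ny)) {
    W <- v * hy * wy[j]
    if (advection_scheme == "central") {
      vec[idx(1L, j)] <- vec[idx(1L, j)] + W * (0.5 - r)
      vec[idx(2L, j)] <- vec[idx(2L, j)] + W * 0.5
      vec[idx(nx - 1L, j)] <- vec[idx(nx - 1L, j)] - W * 0.5
      vec[idx(nx, j)] <- vec[idx(nx, j)] + W * (r - 0.5)
    } else {
      vec[idx(1L, j)] <- vec[idx(1L, j)] + W * (1 - r)
      vec[idx(nx - 1L, j)] <- vec[idx(nx - 1L, j)] - W * 0.5
      vec[idx(nx, j)] <- vec[idx(nx, j)] - W * 0.5
      cpl_coef <- cpl_coef + W * r
    }
  }
  list(vec = vec, cpl_coef = cpl_coef)
}
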