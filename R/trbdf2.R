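# Adaptive one-step implicit integrator for the method-of-lines systems in
# this package: TR-BDF2 (trapezoidal stage + BDF2 stage) with gamma = 2 -
# sqrt(2), which is L-stable and shares one matrix I - (gamma/2) h J between
# both stages (Hosea & Shampine 1996). The embedded 3rd-order companion
# provides the local error estimate; the estimate is filtered through the
# stage matrix so that stiff components do not inflate it.
#
# The environment provides no stiff ODE solver, so this integrator is part
# of the package and is validated against closed-form oracles in the tests
# before the PDE solver relies on it.

.trbdf2_gamma <- 2 - sqrt(2)

# 3rd-order quadrature weights for the embedded error estimate:
# c2 = 1/(6 g (1-g)), c3 = 1/2 - c2 g, c1 = 1 - c2 - c3.
.trbdf2_weights <- local({
  g <- 2 - sqrt(2)
  c2 <- 1 / (6 * g * (1 - g))
  c3 <- 1 / 2 - c2 * g
  c(1 - c2 - c3, c2, c3)
})

#' Adaptive TR-BDF2 integration of a stiff ODE system
#'
#' Integrates dy/dt = f(t, y) from `y0` at `t0` to `t_end`, landing exactly
#' on every requested output time. Each step solves two implicit stages by
#' simplified Newton iteration with a user-supplied analytic Jacobian,
#' factorised sparsely and reused across steps while the step size stays
#' within 25% of the factorised one.
#'
#' @param rhs Function `f(t, y)` returning dy/dt (numeric vector).
#' @param jac Function `J(t, y)` returning the Jacobian df/dy as a (sparse)
#'   Matrix.
#' @param y0 Initial state.
#' @param t0,t_end Integration interval, `t_end > t0`.
#' @param output_times Times at which the solution is recorded (must lie in
#'   `[t0, t_end]`).
#' @param rtol,atol Relative / absolute local error tolerances.
#' @param max_step Optional cap on the step size.
#' @param h0 Initial step size (default `1e-6 * (t_end - t0)`).
#' @return List: `times`, `y` (matrix, one column per output time),
#'   `diagnostics` (step/rejection/Newton/factorisation counts).
#' @keywords internal
#' @export
trbdf2 <- function(rhs, jac, y0, t0 = 0, t_end, output_times,
                   rtol = 1e-6, atol = 1e-12, max_step = Inf, h0 = NULL) {
  stopifnot(t_end > t0, rtol > 0, atol > 0)
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < t0 - 1e-12) || any(output_times > t_end * (1 + 1e-12)))
    stop("trbdf2: output_times must lie in [t0, t_end]")
  g <- .trbdf2_gamma
  d <- g / 2                       # shared implicit coefficient
  cw <- .trbdf2_weights
  n <- length(y0)
  ident <- Matrix::Diagonal(n)

  yout <- matrix(NA_real_, n, length(output_times))
  optr <- 1L
  record <- function(t, y) {
    while (optr <= length(output_times) &&
           output_times[optr] <= t + 1e-9 * max(1, abs(t))) {
      yout[, optr] <<- y
      optr <<- optr + 1L
    }
  }

  t <- t0; y <- as.numeric(y0)
  record(t, y)
  f_n <- rhs(t, y)
  if (any(!is.finite(f_n)))
    stop("trbdf2: non-finite right-hand side at t = ", t)

  span <- t_end - t0
  h <- if (is.null(h0)) 1e-6 * span else h0
  h <- min(h, max_step, span)
  h_min <- 1e-13 * span

  # cached factorisation state
  lu <- NULL; h_fact <- NA_real_; steps_since_jac <- 0L
  n_jac <- 0L; n_lu <- 0L; n_accept <- 0L; n_reject <- 0L; n_newton <- 0L

  refresh <- function(t, y, h) {
    J <- jac(t, y)
    M <- ident - (d * h) * J
    # lu() dispatch needs a general CsparseMatrix; Diagonal-derived classes
    # take a broken solve path in some Matrix versions
    M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
    lu <<- Matrix::lu(M)
    h_fact <<- h
    steps_since_jac <<- 0L
    n_jac <<- n_jac + 1L
    n_lu <<- n_lu + 1L
  }

  newton <- function(t_s, base, guess, sc) {
    y_it <- guess
    nd_prev <- Inf
    for (it in 1:8) {
      n_newton <<- n_newton + 1L
      f_it <- rhs(t_s, y_it)
      gres <- y_it - (d * h_cur) * f_it - base
      if (any(!is.finite(gres))) return(list(ok = FALSE, iters = it))
      dy <- -as.numeric(Matrix::solve(lu, gres))
      y_it <- y_it + dy
      nd <- sqrt(mean((dy / sc)^2))
      if (nd < 5e-2) return(list(ok = TRUE, y = y_it, iters = it))
      if (it > 1 && nd > 0.95 * nd_prev) return(list(ok = FALSE, iters = it))
      nd_prev <- nd
    }
    list(ok = FALSE, iters = 8L)
  }

  h_cur <- h
  while (t < t_end - 1e-9 * max(1, abs(t_end))) {
    # land exactly on the next output time
    t_target <- if (optr <= length(output_times)) output_times[optr] else t_end
    h_cur <- min(h, max_step, t_target - t, t_end - t)
    if (h_cur < h_min)
      stop(sprintf(
        "trbdf2: step size underflow at t = %.6g (last successful time); try tighter rtol/atol or a smaller max_step", t))

    stale <- is.null(lu) || h_cur > 1.25 * h_fact || h_cur < 0.8 * h_fact ||
      steps_since_jac >= 25L
    if (stale) refresh(t, y, h_cur)

    sc <- atol + rtol * abs(y)
    # TR stage
    s1 <- newton(t + g * h_cur, base = y + (d * h_cur) * f_n,
                 guess = y + (g * h_cur) * f_n, sc = sc)
    ok <- s1$ok
    if (ok) {
      yg <- s1$y
      # BDF2 stage
      base2 <- yg / (g * (2 - g)) - ((1 - g)^2 / (g * (2 - g))) * y
      s2 <- newton(t + h_cur, base = base2, guess = yg, sc = sc)
      ok <- s2$ok
    }
    if (!ok) {
      # refresh Jacobian at current point; if that was already fresh, halve h
      if (steps_since_jac > 0L || is.null(lu)) {
        refresh(t, y, h_cur)
      } else {
        h <- h_cur / 2
        n_reject <- n_reject + 1L
      }
      next
    }
    y1 <- s2$y
    f_g <- rhs(t + g * h_cur, yg)
    f_1 <- rhs(t + h_cur, y1)
    est <- y + h_cur * (cw[1] * f_n + cw[2] * f_g + cw[3] * f_1) - y1
    est <- as.numeric(Matrix::solve(lu, est))
    sc2 <- atol + rtol * pmax(abs(y), abs(y1))
    err <- sqrt(mean((est / sc2)^2))
    if (!is.finite(err) || err > 1) {
      n_reject <- n_reject + 1L
      h <- h_cur * max(0.2, 0.9 * err^(-1 / 3))
      next
    }
    # accept
    t <- t + h_cur
    y <- y1
    f_n <- f_1
    n_accept <- n_accept + 1L
    steps_since_jac <- steps_since_jac + 1L
    record(t, y)
    h <- h_cur * min(2.5, max(0.3, 0.9 * err^(-1 / 3)))
  }
  record(t_end, y)

  list(times = output_times, y = yout,
       diagnostics = list(n_accept = n_accept, n_reject = n_reject,
                          n_jac = n_jac, n_lu = n_lu, n_newton = n_newton))
}
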