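# Scripted scenario suite: binding on/off, kinetic and permeability sweeps,
# and spatial snapshot maps, each with named machine-checkable assertions
# of the qualitative behaviour the model is expected to show. All runners
# are deterministic; `nx` and `t_end` are exposed so test suites can run
# reduced grids (the default parameter regime is deep in the well-mixed
# limit, where the centre-point series is grid-insensitive).

#' Copy a parameter object with some fields replaced
#'
#' Convenience for sweeps: returns a new validated object equal to the
#' input except for the named replacements.
#'
#' @param dp,dos The object to copy.
#' @param ... Named replacements (e.g. `B1max = 0`).
#' @return A new `btu_drug_params` / `btu_dosing_params`.
#' @export
modify_drug <- function(dp, ...) {
  d <- unclass(dp)
  repl <- list(...)
  d[names(repl)] <- repl
  do.call(drug_params, d)
}

#' @rdname modify_drug
#' @export
modify_dosing <- function(dos, ...) {
  d <- unclass(dos)
  repl <- list(...)
  d[names(repl)] <- repl
  do.call(dosing_params, d)
}

check_row <- function(name, value, pass) {
  data.frame(name = name, value = value, pass = pass,
             stringsAsFactors = FALSE)
}

# relative slack used when asserting monotone orderings of solver output
# (differences at or below integrator accuracy must not flip a check)
.mono_slack <- 1e-4

#' Binding on/off scenarios
#'
#' Runs the unit with (i) no binding, (ii) specific binding only and
#' (iii) specific + non-specific binding, and checks the expected
#' behaviour: without binding the ECF concentration crosses above the
#' plasma curve after the plasma peak (slow passive exchange), and binding
#' makes the free concentration initially lower but later higher than the
#' no-binding run.
#'
#' @param nx Grid resolution (default 51).
#' @param t_end Final time, s (default 2e5).
#' @param opts [solver_options()].
#' @return List: `results` (named `btu_result`s), `ratio_C_full`,
#'   `ratio_C_spec`, `ratio_B1` (series vs the matching reference run),
#'   `checks` (data.frame name/value/pass).
#' @export
run_binding_scenarios <- function(nx = 51L, t_end = 2e5,
                                  opts = solver_options()) {
  p <- default_params(nx = nx, ny = nx)
  runs <- list(
    none = simulate_unit(modify_drug(p$drug, B1max = 0, B2max = 0),
                         p$dosing, p$domain, t_end, opts = opts),
    specific = simulate_unit(modify_drug(p$drug, B2max = 0),
                             p$dosing, p$domain, t_end, opts = opts),
    full = simulate_unit(p$drug, p$dosing, p$domain, t_end, opts = opts))

  tt <- runs$none$times
  cpl_s <- runs$none$cpl
  i_peak <- which.max(cpl_s)
  C0 <- runs$none$center$C
  Cf <- runs$full$center$C
  floor_ <- 1e-9
  ratio_full <- Cf / pmax(C0, floor_)
  ratio_spec <- runs$specific$center$C / pmax(C0, floor_)
  ratio_B1 <- runs$full$center$B1 / pmax(runs$specific$center$B1, floor_)

  # (a) no-binding C_ECF below Cpl at/before the plasma peak, above after
  below_at_peak <- C0[i_peak] < cpl_s[i_peak]
  after <- seq_along(tt) > i_peak
  crosses_after <- any(C0[after] > cpl_s[after])
  # (b) binding: ratio < 1 during uptake, > 1 late
  early_lo <- ratio_full[i_peak] < 1
  late_hi <- ratio_full[length(tt)] > 1
  checks <- rbind(
    check_row("no_binding_below_cpl_at_peak", C0[i_peak] / cpl_s[i_peak],
              below_at_peak),
    check_row("no_binding_crosses_above_cpl_after_peak",
              max(C0[after] / cpl_s[after]), crosses_after),
    check_row("binding_ratio_below_1_at_cpl_peak", ratio_full[i_peak],
              early_lo),
    check_row("binding_ratio_above_1_late", ratio_full[length(tt)], late_hi),
    check_row("no_nonspecific_run_has_zero_B2",
              max(runs$specific$center$B2), max(runs$specific$center$B2) == 0))
  list(results = runs, times = tt, ratio_C_full = ratio_full,
       ratio_C_spec = ratio_spec, ratio_B1 = ratio_B1, checks = checks)
}

#' Specific-binding kinetics sweep
#'
#' 3 x 3 x 3 grid of runs over k1on x \{0.01, 1, 10\}, k1off x
#' \{0.1, 1, 10\} and B1max x \{0.01, 1, 100\} times their defaults.
#' Monotonicity of the free concentration is asserted at a mid-uptake
#' instant (the first time the default run reaches half its peak) and in
#' the decline phase (three times the default peak time): larger k1on
#' lowers C_ECF during uptake, larger k1off raises it during decline,
#' larger B1max lowers the peak. The k1on ordering carries a 0.1% relative
#' slack because near target saturation (low/default B1max) its effect
#' collapses to zero; the k1off ordering is asserted for k1on multipliers
#' >= 1 only — at very low k1on the uptake and release phases trade off
#' non-monotonically (the combination effect visible in the low-k1on /
#' high-k1off corner of the sweep).
#'
#' @inheritParams run_binding_scenarios
#' @param m_k1on,m_k1off,m_B1max Multiplier vectors (increasing).
#' @return List: `runs` (labelled), `grid` (data.frame of multipliers),
#'   `checks`.
#' @export
run_kinetics_sweep <- function(nx = 51L, t_end = 2e5,
                               m_k1on = c(0.01, 1, 10),
                               m_k1off = c(0.1, 1, 10),
                               m_B1max = c(0.01, 1, 100),
                               opts = solver_options()) {
  p <- default_params(nx = nx, ny = nx)
  grid <- expand.grid(m_k1on = m_k1on, m_k1off = m_k1off, m_B1max = m_B1max)
  grid$label <- sprintf("k1on_x%g.k1off_x%g.B1max_x%g",
                        grid$m_k1on, grid$m_k1off, grid$m_B1max)
  runs <- vector("list", nrow(grid)); names(runs) <- grid$label
  for (r in seq_len(nrow(grid))) {
    dp <- modify_drug(p$drug,
                      k1on = p$drug$k1on * grid$m_k1on[r],
                      k1off = p$drug$k1off * grid$m_k1off[r],
                      B1max = p$drug$B1max * grid$m_B1max[r])
    runs[[r]] <- simulate_unit(dp, p$dosing, p$domain, t_end, opts = opts)
  }
  ref <- simulate_unit(p$drug, p$dosing, p$domain, t_end, opts = opts)
  tt <- ref$times
  t_pk <- tt[which.max(ref$center$C)]
  i_up <- min(which(ref$center$C >= 0.5 * max(ref$center$C)))  # mid-uptake
  i_dn <- which.min(abs(tt - 3 * t_pk))

  C_at <- function(run, i) run$center$C[i]
  checks <- NULL
  # k1on monotone decreasing during uptake; 0.1% slack (effect vanishes
  # once the sparse target pool is saturated)
  slack_on <- 1 + 1e-3
  ok_k1on <- TRUE; worst_k1on <- 1
  for (off in m_k1off) for (bm in m_B1max) {
    cs <- vapply(m_k1on, function(on) {
      C_at(runs[[sprintf("k1on_x%g.k1off_x%g.B1max_x%g", on, off, bm)]], i_up)
    }, numeric(1))
    r <- cs[-1] / (cs[-length(cs)] * slack_on)
    worst_k1on <- max(worst_k1on, r)
    ok_k1on <- ok_k1on && all(cs[-1] <= cs[-length(cs)] * slack_on)
  }
  checks <- rbind(checks, check_row("larger_k1on_lowers_C_uptake",
                                    worst_k1on, ok_k1on))
  # at high target density the k1on effect is strong and strictly ordered
  if (all(c(1, 10) %in% m_k1on) && max(m_B1max) > 1) {
    bm <- max(m_B1max)
    cs <- vapply(c(1, 10), function(on)
      C_at(runs[[sprintf("k1on_x%g.k1off_x1.B1max_x%g", on, bm)]], i_up),
      numeric(1))
    checks <- rbind(checks, check_row("high_B1max_k1on_effect_strict",
                                      cs[2] / cs[1], cs[2] < cs[1]))
  }
  # k1off monotone increasing (decline phase), asserted where association
  # is not rate limiting (k1on multiplier >= 1)
  slack <- 1 + .mono_slack
  ok_k1off <- TRUE; worst_k1off <- 1
  for (on in m_k1on[m_k1on >= 1]) for (bm in m_B1max) {
    cs <- vapply(m_k1off, function(off) {
      C_at(runs[[sprintf("k1on_x%g.k1off_x%g.B1max_x%g", on, off, bm)]], i_dn)
    }, numeric(1))
    r <- (cs[-length(cs)]) / (cs[-1] * slack)
    worst_k1off <- max(worst_k1off, r)
    ok_k1off <- ok_k1off && all(cs[-1] * slack >= cs[-length(cs)])
  }
  checks <- rbind(checks, check_row("larger_k1off_raises_C_decline",
                                    worst_k1off, ok_k1off))
  # B1max lowers the peak
  ok_bm <- TRUE; worst_bm <- 1
  for (on in m_k1on) for (off in m_k1off) {
    pk <- vapply(m_B1max, function(bm) {
      max(runs[[sprintf("k1on_x%g.k1off_x%g.B1max_x%g", on, off, bm)]]$center$C)
    }, numeric(1))
    r <- pk[-1] / (pk[-length(pk)] * slack)
    worst_bm <- max(worst_bm, r)
    ok_bm <- ok_bm && all(pk[-1] <= pk[-length(pk)] * slack)
  }
  checks <- rbind(checks, check_row("larger_B1max_lowers_C_peak",
                                    worst_bm, ok_bm))
  # cap invariant over all runs
  capmax <- max(vapply(seq_len(nrow(grid)), function(r) {
    bm <- p$drug$B1max * grid$m_B1max[r]
    if (bm == 0) 0 else max(runs[[r]]$center$B1) / bm
  }, numeric(1)))
  checks <- rbind(checks, check_row("B1_never_exceeds_B1max", capmax,
                                    capmax <= 1 + 1e-9))
  # faster association fills the dense target pool sooner. At B1max x100
  # the pool capacity (5 umol/L) exceeds the drug the BBB ever delivers, so
  # absolute occupancy plateaus well below 1 (supply-limited, ~0.48 here);
  # the timing claim is therefore tested against 99% of the shared plateau.
  if (all(c(1, 10) %in% m_k1on) && 100 %in% m_B1max && 1 %in% m_k1off) {
    bmax_hi <- p$drug$B1max * 100
    occ_of <- function(lbl) runs[[lbl]]$center$B1 / bmax_hi
    o_fast <- occ_of("k1on_x10.k1off_x1.B1max_x100")
    o_slow <- occ_of("k1on_x1.k1off_x1.B1max_x100")
    thresh <- 0.99 * min(max(o_fast), max(o_slow))
    t_fast <- tt[min(which(o_fast >= thresh))]
    t_slow <- tt[min(which(o_slow >= thresh))]
    checks <- rbind(checks, check_row("high_k1on_saturates_earlier",
                                      t_fast / t_slow, t_fast < t_slow))
  }
  list(runs = runs, reference = ref, grid = grid, checks = checks)
}

#' BBB permeability sweep
#'
#' Runs P x \{0.1, 1, 10\} times the default. A higher permeability makes
#' the ECF profile track the plasma profile closely; a lower one delays and
#' lowers the ECF peak.
#'
#' @inheritParams run_binding_scenarios
#' @param multipliers Permeability multipliers (increasing; default
#'   c(0.1, 1, 10)).
#' @return List: `runs` (named by multiplier), `checks`.
#' @export
run_permeability_sweep <- function(nx = 51L, t_end = 2e5,
                                   multipliers = c(0.1, 1, 10),
                                   opts = solver_options()) {
  p <- default_params(nx = nx, ny = nx)
  runs <- lapply(multipliers, function(m)
    simulate_unit(modify_drug(p$drug, P = p$drug$P * m),
                  p$dosing, p$domain, t_end, opts = opts))
  names(runs) <- sprintf("P_x%g", multipliers)
  tt <- runs[[1]]$times
  t_burn <- 10 * p$domain$xr^2 / p$drug$D_eff
  sel <- tt > t_burn
  track_gap <- vapply(runs, function(r)
    max(abs(r$center$C[sel] - r$cpl[sel])) / max(r$cpl), numeric(1))
  peaks <- vapply(runs, function(r) max(r$center$C), numeric(1))
  t_peaks <- vapply(runs, function(r) tt[which.max(r$center$C)], numeric(1))

  i_lo <- which(multipliers == min(multipliers))
  i_def <- which(multipliers == 1)
  i_hi <- which(multipliers == max(multipliers))
  slack <- 1 + .mono_slack
  checks <- rbind(
    check_row("low_P_peak_later", t_peaks[i_lo] / t_peaks[i_def],
              t_peaks[i_lo] > t_peaks[i_def]),
    check_row("low_P_peak_lower", peaks[i_lo] / peaks[i_def],
              peaks[i_lo] < peaks[i_def]),
    check_row("peak_monotone_in_P", max(peaks[-length(peaks)] / peaks[-1]),
              all(peaks[-1] * slack >= peaks[-length(peaks)])),
    check_row("high_P_tracks_cpl_better", track_gap[i_hi] / track_gap[i_def],
              track_gap[i_hi] < track_gap[i_def]))
  list(runs = runs, track_gap = track_gap, peaks = peaks,
       t_peaks = t_peaks, checks = checks)
}

#' Spatial distribution maps
#'
#' Runs the spatial-experiment preset ([spatial_experiment_params()]:
#' slower diffusion, higher permeability and dose, stronger binding) and
#' stores snapshots bracketing the equilibration of the unit. Default
#' snapshot times are \{0.5, 2, 10\} diffusion times xr^2/D_eff = \{250,
#' 1000, 5000\} s. Early on the concentration rises at the capillary walls
#' and is slightly higher on the left (upstream) side; later diffusion
#' evens everything out.
#'
#' @inheritParams run_binding_scenarios
#' @param snapshot_times Snapshot times, s (default as above).
#' @return List: `result` (with snapshots), `checks`.
#' @export
run_spatial_maps <- function(nx = 51L, snapshot_times = NULL,
                             opts = solver_options()) {
  p <- spatial_experiment_params(nx = nx, ny = nx)
  t_diff <- p$domain$xr^2 / p$drug$D_eff
  if (is.null(snapshot_times)) snapshot_times <- c(0.5, 2, 10) * t_diff
  snapshot_times <- sort(snapshot_times)
  t_end <- max(snapshot_times)
  res <- simulate_unit(p$drug, p$dosing, p$domain, t_end = t_end,
                       output_times = default_output_times(t_end),
                       snapshot_times = snapshot_times, opts = opts)
  s_early <- res$snapshots[[1]]
  s_mid <- res$snapshots[[max(1L, length(res$snapshots) - 1L)]]
  s_late <- res$snapshots[[length(res$snapshots)]]
  nx_ <- p$domain$nx; ny_ <- p$domain$ny

  boundary <- matrix(FALSE, nx_, ny_)
  boundary[c(1, nx_), ] <- TRUE; boundary[, c(1, ny_)] <- TRUE
  contrast <- mean(s_early$C[boundary]) / mean(s_early$C[!boundary])
  xhalf <- seq_len(nx_) <= nx_ / 2
  xright <- seq_len(nx_) > (nx_ + 1) / 2
  lr <- mean(s_early$C[xhalf, ]) / mean(s_early$C[xright, ])
  cv_late <- stats::sd(s_late$C) / mean(s_late$C)
  cv_mid <- stats::sd(s_mid$C) / mean(s_mid$C)
  occ_mid <- min(s_mid$B1) / p$drug$B1max

  checks <- rbind(
    check_row("early_boundary_exceeds_interior", contrast, contrast > 1),
    check_row("early_left_exceeds_right", lr, lr > 1),
    check_row("late_C_evenly_distributed_cv", cv_late, cv_late < 0.01),
    check_row("B1_saturated_while_C_equilibrating",
              occ_mid, occ_mid >= 0.99 && cv_mid > 0.01))
  list(result = res, params = p, checks = checks)
}

#' Non-specific binding proportionality
#'
#' In quasi-equilibrium with C << Kd2 the non-specific pool is linear in
#' the free concentration: B2 ~ (B2max/Kd2) C. Returns the maximum relative
#' deviation of B2 from that line at the unit centre over the times where
#' the quasi-steady-state approximation is valid: t > 10/k2off (the pool
#' has relaxed at least ten times) AND |d ln C / dt| <= k2off / 40 (the
#' free concentration changes at least 40x slower than the pool relaxes;
#' the first-order QSSA error is (d ln C/dt)/k2off, so this caps the lag
#' contribution at ~2.5%, leaving the saturation correction C/Kd2 < 1% on
#' default parameters). During the earliest uptake C grows at ~10%/s
#' relative and no equilibrium description can hold.
#'
#' @param result A `btu_result`.
#' @param floor Concentration floor, umol/L, below which times are skipped.
#' @return Maximum relative deviation |B2 - kp C| / (kp C) with
#'   kp = B2max * k2on / k2off, over the tested times. Attribute
#'   `kp` carries the proportionality constant.
#' @export
proportionality_check <- function(result, floor = 1e-6) {
  stopifnot(inherits(result, "btu_result"))
  dp <- result$dp
  if (dp$k2on <= 0 || dp$k2off <= 0)
    stop("proportionality_check: needs k2on, k2off > 0")
  kp <- dp$B2max * dp$k2on / dp$k2off
  tt <- result$times; Cc <- result$center$C
  # centred finite-difference relative growth rate of C; endpoints of the
  # usable window stay excluded (Inf) for lack of a centred estimate
  dln <- rep(Inf, length(tt))
  pos <- Cc > floor
  i2 <- which(pos)
  if (length(i2) > 2) {
    ii <- i2[-c(1, length(i2))]
    dln[ii] <- abs(log(Cc[i2[-(1:2)]]) - log(Cc[i2[1:(length(i2) - 2)]])) /
      (tt[i2[-(1:2)]] - tt[i2[1:(length(i2) - 2)]])
  }
  sel <- tt > 10 / dp$k2off & pos & dln <= dp$k2off / 40
  if (!any(sel)) stop("proportionality_check: no usable late times")
  dev <- max(abs(result$center$B2[sel] - kp * Cc[sel]) / (kp * Cc[sel]))
  attr(dev, "kp") <- kp
  dev
}
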