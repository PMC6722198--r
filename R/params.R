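#' Transport and binding constants for a drug in brain ECF
#'
#' Bundles the drug-specific and tissue-specific constants that enter the
#' brain-tissue-unit model: effective diffusion, bulk flow, BBB permeability,
#' and two classes of reversible binding sites (specific/target and
#' non-specific). Units follow the field's convention: lengths in m, time in
#' s, concentrations in umol/L.
#'
#' @param D_eff Effective diffusion coefficient D* in brain ECF, m^2/s.
#'   Related to the free diffusion coefficient D by the tortuosity lambda via
#'   D* = D / lambda^2 (see [tortuosity_to_Deff()]).
#' @param v Brain ECF bulk-flow speed along +x, m/s.
#' @param P BBB permeability, m/s (passive, bidirectional).
#' @param k1on,k1off,B1max Specific (target) binding: association rate
#'   constant (umol/L s)^-1, dissociation rate constant s^-1, and total
#'   binding-site concentration umol/L.
#' @param k2on,k2off,B2max Non-specific analogues, same units.
#' @return An object of class `btu_drug_params` (named list).
#' @seealso [default_params()], [dosing_params()], [domain2d()]
#' @export
drug_params <- function(D_eff, v, P, k1on, k1off, B1max, k2on, k2off, B2max) {
  p <- list(D_eff = D_eff, v = v, P = P,
            k1on = k1on, k1off = k1off, B1max = B1max,
            k2on = k2on, k2off = k2off, B2max = B2max)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("drug_params: '", nm, "' must be a single finite number")
    if (x < 0)
      stop("drug_params: '", nm, "' must be >= 0 (got ", x, ")")
  }
  if (!is.finite(p$B1max) || !is.finite(p$B2max))
    stop("drug_params: B1max and B2max must be finite")
  structure(p, class = "btu_drug_params")
}

#' Plasma forcing constants (dosing)
#'
#' Parameters of the closed-form plasma concentration profile that drives the
#' boundary condition: single oral or intravenous dose with first-order
#' absorption (ka) and elimination (ke).
#'
#' @param route `"oral"` (two-exponential Bateman-type profile) or `"iv"`
#'   (mono-exponential decay from C0 = Dose/V).
#' @param F_bio Bioavailability, dimensionless in \[0, 1\].
#' @param Dose Molar amount administered, umol.
#' @param ka Absorption rate constant, s^-1.
#' @param ke Elimination rate constant, s^-1.
#' @param V Distribution volume, L.
#' @return An object of class `btu_dosing_params`.
#' @export
dosing_params <- function(route = "oral", F_bio = 1, Dose, ka, ke, V) {
  route <- match.arg(route, c("oral", "iv"))
  num <- list(F_bio = F_bio, Dose = Dose, ka = ka, ke = ke, V = V)
  for (nm in names(num)) {
    x <- num[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop("dosing_params: '", nm, "' must be a single finite number")
    if (x < 0) stop("dosing_params: '", nm, "' must be >= 0 (got ", x, ")")
  }
  if (F_bio > 1) stop("dosing_params: F_bio must lie in [0, 1]")
  if (Dose <= 0) stop("dosing_params: Dose must be > 0")
  if (V <= 0) stop("dosing_params: V must be > 0")
  structure(list(route = route, F_bio = F_bio, Dose = Dose,
                 ka = ka, ke = ke, V = V),
            class = "btu_dosing_params")
}

#' Geometry of the 2D brain tissue unit
#'
#' The unit is the square of ECF between neighbouring capillaries, with
#' (0,0) the lower-left corner; in rat brain the capillary spacing averages
#' 50 um, hence the default extents. Nodes are placed on a uniform grid with
#' boundary nodes exactly on the capillary walls.
#'
#' @param xr,yr Side lengths, m.
#' @param nx,ny Node counts per axis (>= 3).
#' @return An object of class `btu_domain` with spacings `hx`, `hy`.
#' @export
domain2d <- function(xr = 50e-6, yr = 50e-6, nx = 51L, ny = 51L) {
  if (!is.numeric(xr) || !is.numeric(yr) || xr <= 0 || yr <= 0)
    stop("domain2d: xr and yr must be > 0")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 3L || ny < 3L)
    stop("domain2d: nx and ny must be integers >= 3")
  structure(list(xr = xr, yr = yr, nx = nx, ny = ny,
                 hx = xr / (nx - 1L), hy = yr / (ny - 1L)),
            class = "btu_domain")
}

#' @export
print.btu_drug_params <- function(x, ...) {
  cat("Brain-tissue-unit drug parameters\n")
  cat(sprintf("  transport: D_eff = %g m^2/s, v = %g m/s, P = %g m/s\n",
              x$D_eff, x$v, x$P))
  cat(sprintf("  specific binding:     k1on = %g (umol/L s)^-1, k1off = %g s^-1, B1max = %g umol/L (Kd1 = %g)\n",
              x$k1on, x$k1off, x$B1max,
              if (x$k1on > 0) x$k1off / x$k1on else NA_real_))
  cat(sprintf("  non-specific binding: k2on = %g (umol/L s)^-1, k2off = %g s^-1, B2max = %g umol/L (Kd2 = %g)\n",
              x$k2on, x$k2off, x$B2max,
              if (x$k2on > 0) x$k2off / x$k2on else NA_real_))
  invisible(x)
}

#' @export
print.btu_dosing_params <- function(x, ...) {
  cat(sprintf("Dosing: route = %s, F = %g, Dose = %g umol, ka = %g s^-1, ke = %g s^-1, V = %g L\n",
              x$route, x$F_bio, x$Dose, x$ka, x$ke, x$V))
  invisible(x)
}

#' @export
print.btu_domain <- function(x, ...) {
  cat(sprintf("Domain: %g x %g um, grid %d x %d (h = %g x %g um)\n",
              x$xr * 1e6, x$yr * 1e6, x$nx, x$ny, x$hx * 1e6, x$hy * 1e6))
  invisible(x)
}

#' Default parameter preset
#'
#' The canonical parameter set used throughout the scenario suite unless a
#' sweep overrides individual values. All values sit inside the physiological
#' ranges of [physiological_ranges()] where literature data exist; the
#' non-specific binding constants are modelling assumptions (k2on a factor
#' 100 lower than k1on, k2off a factor 100 higher than k1off, B2max a factor
#' 1000 higher than B1max) because measured values are lacking.
#'
#' @param nx,ny Grid resolution for the returned domain (defaults 51).
#' @return A list with elements `drug` ([drug_params()]), `dosing`
#'   ([dosing_params()]), `domain` ([domain2d()]).
#' @export
default_params <- function(nx = 51L, ny = 51L) {
  list(
    drug = drug_params(D_eff = 5e-11, v = 5e-7, P = 1e-9,
                       k1on = 1, k1off = 1e-2, B1max = 5e-2,
                       k2on = 1e-2, k2off = 1, B2max = 50),
    dosing = dosing_params(route = "oral", F_bio = 1, Dose = 30,
                           ka = 2e-4, ke = 5e-5, V = 20),
    domain = domain2d(xr = 50e-6, yr = 50e-6, nx = nx, ny = ny)
  )
}

#' Spatial-experiment parameter preset
#'
#' Default preset with slower diffusion, larger dose, higher permeability and
#' stronger/denser binding, chosen to make local concentration differences
#' within the unit visible in the spatial snapshot scenario.
#'
#' @inheritParams default_params
#' @return Same structure as [default_params()].
#' @export
spatial_experiment_params <- function(nx = 51L, ny = 51L) {
  p <- default_params(nx = nx, ny = ny)
  d <- unclass(p$drug)
  d$D_eff <- 5e-12
  d$P <- 1e-7
  d$k1on <- 10
  d$B1max <- 1e-1
  d$B2max <- 100
  p$drug <- do.call(drug_params, d)
  dos <- unclass(p$dosing)
  dos$Dose <- 100
  p$dosing <- do.call(dosing_params, dos)
  p
}

#' Physiological ranges of the model parameters
#'
#' Literature-based (rat) ranges used by [validate_params()]. No ranges exist
#' for the non-specific binding constants (k2on, k2off, B2max): the
#' literature lacks measured values, so those parameters are reported as
#' "unchecked". The elimination-rate row is stored exactly as printed in the
#' source table (low = 1e-1 > high = 5e-3) and flagged `inconsistent`; it is
#' reported but never treated as a hard bound.
#'
#' @return A data.frame with columns `param`, `unit`, `low`, `high`,
#'   `inconsistent`.
#' @export
physiological_ranges <- function() {
  data.frame(
    param = c("D_eff", "v", "P", "B1max", "k1on", "k1off",
              "F_bio", "Dose", "ka", "ke", "V"),
    unit = c("m^2/s", "m/s", "m/s", "umol/L", "(umol/L s)^-1", "s^-1",
             "-", "umol", "s^-1", "s^-1", "L"),
    low  = c(1e-11, 5e-8, 1e-10, 1e-3, 1e-4, 1e-6, 0, 1e-1, 0, 1e-1, 0.01),
    high = c(1e-10, 5e-6, 1e-5, 5e-1, 1e3, 1e1, 1, 5e3, 2e-3, 5e-3, 50e3),
    inconsistent = c(rep(FALSE, 9), TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Check a parameter set against physiological ranges
#'
#' Negative values are hard errors (already rejected by the constructors);
#' out-of-range values only warn, because sensitivity sweeps deliberately
#' exceed the ranges (e.g. B1max x100). Parameters with no literature range
#' are reported as `unchecked`.
#'
#' @param dp A [drug_params()] object.
#' @param dos A [dosing_params()] object.
#' @param ranges Range table, default [physiological_ranges()].
#' @param warn Emit an R warning listing out-of-range parameters (default
#'   TRUE).
#' @return A data.frame report with columns `param`, `value`, `status`
#'   (`"in-range"`, `"out-of-range"`, `"unchecked"`) and `flagged` (TRUE for
#'   rows whose stored range is known-inconsistent), invisibly classed
#'   `btu_validation`.
#' @export
validate_params <- function(dp, dos, ranges = physiological_ranges(),
                            warn = TRUE) {
  stopifnot(inherits(dp, "btu_drug_params"), inherits(dos, "btu_dosing_params"))
  vals <- c(unclass(dp)[c("D_eff", "v", "P", "B1max", "k1on", "k1off",
                          "k2on", "k2off", "B2max")],
            unclass(dos)[c("F_bio", "Dose", "ka", "ke", "V")])
  for (nm in names(vals)) {
    if (vals[[nm]] < 0) stop("validate_params: '", nm, "' is negative")
  }
  status <- character(length(vals)); flagged <- logical(length(vals))
  for (i in seq_along(vals)) {
    nm <- names(vals)[i]
    row <- ranges[ranges$param == nm, , drop = FALSE]
    if (nrow(row) == 0L) {
      status[i] <- "unchecked"
    } else {
      flagged[i] <- isTRUE(row$inconsistent)
      lo <- min(row$low, row$high); hi <- max(row$low, row$high)
      status[i] <- if (vals[[nm]] >= lo && vals[[nm]] <= hi)
        "in-range" else "out-of-range"
    }
  }
  rep <- data.frame(param = names(vals), value = unlist(vals),
                    status = status, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  bad <- rep$param[rep$status == "out-of-range"]
  if (warn && length(bad))
    warning("parameters outside physiological range: ",
            paste(bad, collapse = ", "), call. = FALSE)
  class(rep) <- c("btu_validation", class(rep))
  rep
}

#' Effective diffusion coefficient from tortuosity
#'
#' Diffusion through brain ECF is hindered by cells and extracellular matrix;
#' the tortuosity lambda = sqrt(D / D*) relates the free diffusion
#' coefficient D to the effective one, so D* = D / lambda^2.
#'
#' @param D Free diffusion coefficient, m^2/s (> 0).
#' @param lam Tortuosity, dimensionless (> 0).
#' @return Effective diffusion coefficient D*, m^2/s.
#' @export
tortuosity_to_Deff <- function(D, lam) {
  if (!is.numeric(D) || any(D <= 0)) stop("tortuosity_to_Deff: D must be > 0")
  if (!is.numeric(lam) || any(lam <= 0))
    stop("tortuosity_to_Deff: lam must be > 0")
  D / lam^2
}
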