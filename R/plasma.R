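# Closed-form plasma concentration profiles used as boundary forcing.
# Plasma is assumed independent of the tissue state: the brain is a small
# sink relative to the body, so no feedback term exists anywhere.

#' Plasma concentration after an intravenous bolus
#'
#' C_pl(t) = (Dose/V) * exp(-ke t): instantaneous mixing into the
#' distribution volume followed by first-order elimination.
#'
#' @param t Time(s) since dosing, s (vectorised, all >= 0).
#' @param dos A [dosing_params()] object.
#' @return Plasma concentration(s), umol/L.
#' @export
cpl_iv <- function(t, dos) {
  stopifnot(inherits(dos, "btu_dosing_params"))
  if (any(t < 0)) stop("cpl_iv: t must be >= 0")
  (dos$Dose / dos$V) * exp(-dos$ke * t)
}

#' Plasma concentration after a single oral dose
#'
#' Bateman-type two-exponential profile:
#' C_pl(t) = F Dose ka / (V (ka - ke)) * (exp(-ke t) - exp(-ka t)),
#' rising with absorption (ka) and falling with elimination (ke). The
#' ka = ke singularity is removable; within a relative tolerance of 1e-8 the
#' continuous extension F Dose ka t exp(-ka t) / V is used instead, so
#' parameter sweeps over ka are safe.
#'
#' @inheritParams cpl_iv
#' @return Plasma concentration(s), umol/L.
#' @export
cpl_oral <- function(t, dos) {
  stopifnot(inherits(dos, "btu_dosing_params"))
  if (any(t < 0)) stop("cpl_oral: t must be >= 0")
  ka <- dos$ka; ke <- dos$ke
  scale <- dos$F_bio * dos$Dose / dos$V
  if (abs(ka - ke) <= 1e-8 * max(ka, ke)) {
    scale * ka * t * exp(-ka * t)
  } else {
    scale * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Plasma concentration (route dispatch)
#'
#' Dispatches to [cpl_oral()] or [cpl_iv()] according to `dos$route`.
#'
#' @inheritParams cpl_iv
#' @return Plasma concentration(s), umol/L.
#' @export
cpl <- function(t, dos) {
  stopifnot(inherits(dos, "btu_dosing_params"))
  switch(dos$route,
         oral = cpl_oral(t, dos),
         iv = cpl_iv(t, dos),
         stop("cpl: unknown route '", dos$route, "'"))
}

#' Time and height of the oral plasma peak
#'
#' For ka != ke the unique maximiser of the oral profile is
#' t* = ln(ka/ke) / (ka - ke); for ka = ke it is 1/ka.
#'
#' @param dos A [dosing_params()] object (oral constants used).
#' @return List with `t_peak` (s) and `c_peak` (umol/L).
#' @export
cpl_oral_peak <- function(dos) {
  stopifnot(inherits(dos, "btu_dosing_params"))
  ka <- dos$ka; ke <- dos$ke
  if (ka <= 0) stop("cpl_oral_peak: ka must be > 0")
  t_peak <- if (abs(ka - ke) <= 1e-8 * max(ka, ke)) 1 / ka
            else log(ka / ke) / (ka - ke)
  list(t_peak = t_peak, c_peak = cpl_oral(t_peak, dos))
}
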