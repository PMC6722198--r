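# Reaction terms for reversible drug binding in the ECF. Binding sites are
# immobile and evenly distributed, so B1/B2 carry no transport terms; their
# spatial pattern arises only through the local free concentration.

#' Binding reaction rates
#'
#' Mass-action kinetics for two classes of reversible binding sites:
#' dB1/dt = k1on C (B1max - B1) - k1off B1 (specific/target, saturable),
#' dB2/dt = k2on C (B2max - B2) - k2off B2 (non-specific, high capacity),
#' and the matching loss from free drug dC = -(dB1 + dB2). The three rates
#' sum to zero exactly (local mass conservation of the reaction). No
#' positivity clamping is applied: smoothness matters for the implicit
#' integrator and positivity is checked on solver output instead.
#'
#' @param C,B1,B2 Free, target-bound and non-specifically-bound
#'   concentrations, umol/L (vectorised, same length).
#' @param dp A [drug_params()] object.
#' @return List with components `dC`, `dB1`, `dB2` in umol/L/s.
#' @export
binding_rhs <- function(C, B1, B2, dp) {
  dB1 <- dp$k1on * C * (dp$B1max - B1) - dp$k1off * B1
  dB2 <- dp$k2on * C * (dp$B2max - B2) - dp$k2off * B2
  list(dC = -(dB1 + dB2), dB1 = dB1, dB2 = dB2)
}

#' Equilibrium bound concentration
#'
#' Stationary point of the binding ODE at fixed free concentration C:
#' B = Bmax C / (Kd + C) with Kd = koff/kon (a Langmuir isotherm). For
#' kon = 0 no complex forms and the equilibrium is 0.
#'
#' @param C Free concentration, umol/L (vectorised).
#' @param Bmax Total binding-site concentration, umol/L.
#' @param kon Association rate constant, (umol/L s)^-1.
#' @param koff Dissociation rate constant, s^-1.
#' @return Equilibrium bound concentration, umol/L.
#' @export
equilibrium_bound <- function(C, Bmax, kon, koff) {
  if (kon < 0 || koff < 0) stop("equilibrium_bound: rate constants must be >= 0")
  if (kon == 0 && koff == 0)
    stop("equilibrium_bound: kon = koff = 0, equilibrium undefined")
  if (kon == 0) return(rep(0, length(C)))
  Bmax * C / (koff / kon + C)
}

#' Fractional occupancy of a binding-site class
#'
#' @param B Bound concentration, umol/L.
#' @param Bmax Total site concentration, umol/L.
#' @return B/Bmax in \[0, 1\]; 0 when Bmax = 0.
#' @export
occupancy <- function(B, Bmax) {
  if (Bmax == 0) return(rep(0, length(B)))
  B / Bmax
}
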