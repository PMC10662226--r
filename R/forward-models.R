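## Forward models: FvCB limitation functions, C4 PEPc-limited assimilation,
## the four-parameter non-rectangular hyperbola, and the derived scalar
## quantities (iWUE, NPQ, Fv/Fm).

## internal parameterizations taking gammastar/Km directly
.fvcbAcRaw <- function(ci, Vcmax, Rd, gammastar, Km) {
  Vcmax * (ci - gammastar) / (ci + Km) - Rd
}

.fvcbAjRaw <- function(ci, J, Rd, gammastar) {
  J * (ci - gammastar) / (4 * ci + 8 * gammastar) - Rd
}

#' Rubisco-limited net assimilation (FvCB)
#'
#' \eqn{A_c = V_{cmax} (c_i - \Gamma^*) / (c_i + K_m) - R_d}, with
#' \eqn{K_m = K_c (1 + O/K_o)} from \code{constants}. Strictly increasing in
#' ci and equal to \eqn{-R_d} at the compensation point
#' \eqn{c_i = \Gamma^*}.
#'
#' @param ci Intercellular CO2 concentration (umol mol-1), vectorised.
#' @param Vcmax Maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param Rd Day respiration (umol m-2 s-1).
#' @param constants A \linkS4class{KineticConstants} object.
#' @return Net assimilation (umol m-2 s-1).
#' @examples
#' fvcbAc(300, Vcmax = 100, Rd = 1.5)  # ~23.96
#' @export
fvcbAc <- function(ci, Vcmax, Rd, constants = kineticConstants()) {
  stopifnot(all(ci >= 0))
  .fvcbAcRaw(ci, Vcmax, Rd, constants@gammastar, kmOf(constants))
}

#' RuBP-regeneration-limited net assimilation (FvCB)
#'
#' \eqn{A_j = J (c_i - \Gamma^*) / (4 c_i + 8 \Gamma^*) - R_d}; approaches
#' \eqn{J/4 - R_d} as ci grows.
#'
#' @param J Electron transport rate (umol m-2 s-1).
#' @inheritParams fvcbAc
#' @return Net assimilation (umol m-2 s-1).
#' @export
fvcbAj <- function(ci, J, Rd, constants = kineticConstants()) {
  stopifnot(all(ci >= 0))
  .fvcbAjRaw(ci, J, Rd, constants@gammastar)
}

#' FvCB net assimilation: minimum of the two limitations
#'
#' @inheritParams fvcbAc
#' @param Jmax Maximum electron transport rate (umol m-2 s-1).
#' @return min(Ac, Aj) at each ci.
#' @export
fvcbAssimilation <- function(ci, Vcmax, Jmax, Rd,
                             constants = kineticConstants()) {
  pmin(fvcbAc(ci, Vcmax, Rd, constants), fvcbAj(ci, Jmax, Rd, constants))
}

#' PEPc-limited net assimilation (C4 initial slope)
#'
#' \eqn{A = V_{pmax} c_i / (c_i + K_p) - R_d}: Michaelis-Menten response of
#' PEP carboxylation to CO2, governing the low-ci region of the C4 A/ci
#' curve. Equals \eqn{V_{pmax}/2 - R_d} at \eqn{c_i = K_p} and approaches
#' \eqn{V_{pmax} - R_d} at saturating ci.
#'
#' @param ci Intercellular CO2 (umol mol-1), vectorised.
#' @param Vpmax Maximum PEPc carboxylation rate (umol m-2 s-1).
#' @param Kp PEPc Michaelis constant for CO2 (umol mol-1).
#' @param Rd Day respiration (umol m-2 s-1).
#' @return Net assimilation (umol m-2 s-1).
#' @export
c4PepcLimited <- function(ci, Vpmax, Kp, Rd) {
  stopifnot(all(ci >= 0))
  Vpmax * ci / (ci + Kp) - Rd
}

#' Four-parameter non-rectangular hyperbola
#'
#' \deqn{A(c_i) = \frac{\phi c_i + A_{sat} -
#'   \sqrt{(\phi c_i + A_{sat})^2 - 4 \theta \phi c_i A_{sat}}}{2\theta}
#'   + \mathrm{offset}}
#' The horizontal asymptote is \eqn{A_{sat} + \mathrm{offset}}; at
#' \eqn{c_i = 0} the value is the offset; as \eqn{\theta \to 0} the curve
#' tends to the rectangular hyperbola
#' \eqn{\phi c_i A_{sat}/(\phi c_i + A_{sat}) + \mathrm{offset}}.
#'
#' @param ci Intercellular CO2 (umol mol-1), vectorised.
#' @param phi Initial slope (mol mol-1).
#' @param Asat Saturation amplitude (umol m-2 s-1).
#' @param theta Curvature in (0, 1].
#' @param offset Vertical offset (umol m-2 s-1).
#' @return Net assimilation (umol m-2 s-1).
#' @export
nonRectHyperbola <- function(ci, phi, Asat, theta, offset = 0) {
  z <- phi * ci + Asat
  disc <- pmax(z^2 - 4 * theta * phi * ci * Asat, 0)
  (z - sqrt(disc)) / (2 * theta) + offset
}

#' Intrinsic water use efficiency
#'
#' iWUE = A / gs (umol CO2 per mol H2O). Requires gs > 0.
#'
#' @param A Net assimilation (umol m-2 s-1), vectorised.
#' @param gs Stomatal conductance to water vapour (mol m-2 s-1).
#' @return iWUE (umol mol-1).
#' @examples
#' computeIwue(30, 0.3)  # 100
#' @export
computeIwue <- function(A, gs) {
  if (any(!is.finite(gs)) || any(gs <= 0))
    stop("iWUE undefined: gs must be positive")
  A / gs
}

#' Non-photochemical quenching from maximal fluorescence
#'
#' NPQ = (Fm - Fm') / Fm'. Not clipped: transiently negative values (Fm'
#' above the dark-adapted Fm) are returned as-is.
#'
#' @param Fm Dark-adapted maximal fluorescence.
#' @param FmPrime Light-adapted maximal fluorescence (> 0), vectorised.
#' @return NPQ (dimensionless).
#' @examples
#' computeNpq(2, 1)    # 1
#' computeNpq(1.8, 0.6)  # 2
#' @export
computeNpq <- function(Fm, FmPrime) {
  if (any(!is.finite(FmPrime)) || any(FmPrime <= 0))
    stop("NPQ undefined: Fm' must be positive")
  (Fm - FmPrime) / FmPrime
}

#' Maximum quantum efficiency of photosystem II
#'
#' Fv/Fm = (Fm - Fo) / Fm, in (0, 1).
#'
#' @param Fm Dark-adapted maximal fluorescence (> 0).
#' @param Fo Dark-adapted minimal fluorescence (0 < Fo < Fm).
#' @return Fv/Fm.
#' @examples
#' computeFvFm(2, 0.4)  # 0.8
#' @export
computeFvFm <- function(Fm, Fo) {
  if (any(Fm <= 0)) stop("Fm must be positive")
  if (any(Fo <= 0) || any(Fo >= Fm))
    stop("Fv/Fm undefined: Fo must satisfy 0 < Fo < Fm")
  (Fm - Fo) / Fm
}
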