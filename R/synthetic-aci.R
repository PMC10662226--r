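## Synthetic A/ci curve generation for C3 and C4 leaves.

#' Default CO2 setpoint sequences
#'
#' The C3 (tomato/barley) protocol logs eleven reference-CO2 setpoints, with
#' the repeated 400 umol mol-1 points retained as distinct observations. The
#' C4 (maize) protocol ascends through five setpoints, returns to 400 and
#' descends through seven.
#'
#' @return Numeric vector of setpoints (umol mol-1); for
#'   \code{co2SequenceC4()} a list with components \code{up} and
#'   \code{down}.
#' @export
co2SequenceC3 <- function() {
  c(400, 300, 200, 100, 50, 400, 400, 700, 1000, 1300, 1800)
}

#' @rdname co2SequenceC3
#' @export
co2SequenceC4 <- function() {
  list(up = c(400, 600, 800, 1000, 1250),
       down = c(400, 300, 250, 200, 100, 75, 25))
}

#' True generating parameters for a synthetic C3 leaf
#'
#' @param Vcmax,Jmax,Rd Capacities and day respiration (umol m-2 s-1).
#' @param gammastar CO2 compensation point (umol mol-1).
#' @param Km Effective Michaelis constant (umol mol-1); defaults to the
#'   value implied by [kineticConstants()].
#' @return Named list of class \code{c3TrueParams}.
#' @export
c3TrueParams <- function(Vcmax = 100, Jmax = 180, Rd = 1.5,
                         gammastar = 42.75, Km = kmOf(kineticConstants())) {
  stopifnot(Vcmax > 0, Jmax > 0, Rd >= 0, gammastar > 0, Km > 0)
  structure(list(Vcmax = Vcmax, Jmax = Jmax, Rd = Rd,
                 gammastar = gammastar, Km = Km),
            class = "c3TrueParams")
}

#' True generating parameters for a synthetic C4 leaf
#'
#' @param Vpmax Maximum PEPc carboxylation rate (umol m-2 s-1).
#' @param Kp PEPc Michaelis constant for CO2 (umol mol-1).
#' @param Amax CO2- and light-saturated assimilation: the horizontal
#'   asymptote of the saturating hyperbola (umol m-2 s-1).
#' @param phi Initial slope of the hyperbola (mol mol-1).
#' @param theta Curvature, in (0, 1].
#' @param Rd Day respiration (umol m-2 s-1).
#' @return Named list of class \code{c4TrueParams}.
#' @export
c4TrueParams <- function(Vpmax = 110, Kp = 80, Amax = 45, phi = 0.55,
                         theta = 0.7, Rd = 2) {
  stopifnot(Vpmax > 0, Kp > 0, Amax > 0, phi > 0, theta > 0, theta <= 1,
            Rd >= 0)
  structure(list(Vpmax = Vpmax, Kp = Kp, Amax = Amax, phi = phi,
                 theta = theta, Rd = Rd),
            class = "c4TrueParams")
}

.checkAciGenArgs <- function(setpoints, noiseSd) {
  if (!length(setpoints) || any(!is.finite(setpoints)) || any(setpoints <= 0))
    stop("CO2 setpoints must be positive and non-empty")
  if (!is.finite(noiseSd) || noiseSd < 0)
    stop("noiseSd must be non-negative")
}

#' Generate a synthetic C3 A/ci curve
#'
#' ci is derived from each CO2 setpoint through a fixed affine drawdown
#' (\code{ci = drawdown * setpoint}, default drawdown 0.7, plus a small
#' Gaussian jitter); net assimilation is the FvCB forward model
#' min(Ac, Aj) evaluated at that ci plus additive Gaussian noise; stomatal
#' conductance is a configurable baseline with small noise. With
#' \code{noiseSd = 0} and \code{ciJitterSd = 0} every point lies exactly on
#' the forward model. Fully deterministic given \code{seed}.
#'
#' @param params A [c3TrueParams()] list.
#' @param co2Sequence CO2 setpoints in measurement order (umol mol-1).
#' @param noiseSd Additive Gaussian noise SD on A (umol m-2 s-1).
#' @param seed Integer seed.
#' @param drawdown Affine ci drawdown fraction applied to the setpoint.
#' @param ciJitterSd SD of the Gaussian jitter on ci (umol mol-1).
#' @param gsBaseline,gsNoiseSd Baseline stomatal conductance and its noise
#'   SD (mol m-2 s-1).
#' @param species,treatment,timeOfDay,replicateId Metadata for the returned
#'   curve.
#' @return An \linkS4class{ACiCurve}.
#' @examples
#' curve <- generateAciC3(noiseSd = 0, ciJitterSd = 0, seed = 1)
#' nrow(aciPoints(curve))  # 11
#' @export
generateAciC3 <- function(params = c3TrueParams(),
                          co2Sequence = co2SequenceC3(),
                          noiseSd = 0.3, seed = 1L, drawdown = 0.7,
                          ciJitterSd = 2, gsBaseline = 0.3,
                          gsNoiseSd = 0.01, species = "tomato",
                          treatment = "attached", timeOfDay = "AM",
                          replicateId = "r1") {
  .checkAciGenArgs(co2Sequence, noiseSd)
  n <- length(co2Sequence)
  .withSeed(childSeed(seed, "aci_c3", replicateId), {
    ci <- pmax(drawdown * co2Sequence + rnorm(n, 0, ciJitterSd), 1)
    A <- .fvcbAcRaw(ci, params$Vcmax, params$Rd, params$gammastar, params$Km)
    A <- pmin(A, .fvcbAjRaw(ci, params$Jmax, params$Rd, params$gammastar))
    A <- A + rnorm(n, 0, noiseSd)
    gs <- pmax(gsBaseline + rnorm(n, 0, gsNoiseSd), 1e-4)
    aciCurve(data.frame(co2_set = co2Sequence, ci = ci, A = A, gs = gs),
             species = species, treatment = treatment,
             timeOfDay = timeOfDay, replicateId = replicateId)
  })
}

#' Generate a synthetic C4 A/ci curve
#'
#' Points for the ascending then descending setpoint sequences are
#' concatenated in measurement order. Net assimilation is the minimum of
#' the PEPc-limited rate and the saturating non-rectangular hyperbola
#' (asymptote \code{Amax}, evaluated with Asat = Amax + Rd and
#' offset = -Rd), plus additive Gaussian noise. ci uses the same affine
#' drawdown construction as [generateAciC3()] with a default C4 drawdown
#' of 0.4.
#'
#' @param params A [c4TrueParams()] list.
#' @param upSequence,downSequence Ascending and descending CO2 setpoints
#'   (umol mol-1).
#' @inheritParams generateAciC3
#' @return An \linkS4class{ACiCurve}.
#' @examples
#' curve <- generateAciC4(noiseSd = 0, ciJitterSd = 0, seed = 1)
#' nrow(aciPoints(curve))  # 12
#' @export
generateAciC4 <- function(params = c4TrueParams(),
                          upSequence = co2SequenceC4()$up,
                          downSequence = co2SequenceC4()$down,
                          noiseSd = 0.3, seed = 1L, drawdown = 0.4,
                          ciJitterSd = 2, gsBaseline = 0.2,
                          gsNoiseSd = 0.008, species = "maize",
                          treatment = "attached", timeOfDay = "AM",
                          replicateId = "r1") {
  setpoints <- c(upSequence, downSequence)
  .checkAciGenArgs(setpoints, noiseSd)
  n <- length(setpoints)
  .withSeed(childSeed(seed, "aci_c4", replicateId), {
    ci <- pmax(drawdown * setpoints + rnorm(n, 0, ciJitterSd), 1)
    A <- pmin(
      c4PepcLimited(ci, params$Vpmax, params$Kp, params$Rd),
      nonRectHyperbola(ci, params$phi, params$Amax + params$Rd,
                       params$theta, offset = -params$Rd)
    ) + rnorm(n, 0, noiseSd)
    gs <- pmax(gsBaseline + rnorm(n, 0, gsNoiseSd), 1e-4)
    aciCurve(data.frame(co2_set = setpoints, ci = ci, A = A, gs = gs),
             species = species, treatment = treatment,
             timeOfDay = timeOfDay, replicateId = replicateId)
  })
}
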