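## Synthetic NPQ pulse-trace generation.

#' Default saturating-pulse protocol
#'
#' Twelve saturating pulses across a 10 min actinic-light induction phase
#' (evenly spaced, first pulse at light-on so the induction model passes
#' through NPQ = 0) and eight pulses across a 12 min dark relaxation phase
#' (denser early, when relaxation is fastest; times re-zeroed at
#' light-off).
#'
#' @return List with numeric components \code{induction} and
#'   \code{relaxation} (pulse times, minutes since phase start).
#' @export
npqProtocol <- function() {
  list(induction = seq(0, 10, length.out = 12),
       relaxation = c(0.5, 1, 2, 3, 5, 7, 9, 12))
}

#' Generate a synthetic NPQ pulse trace
#'
#' True NPQ at each induction pulse time follows the saturating-exponential
#' induction model \eqn{NPQ = a_{ind}(1 - e^{-b_{ind} t})}; at each
#' relaxation pulse time (re-zeroed at light-off) it follows the decaying
#' exponential \eqn{NPQ = a_{rel} e^{-b_{rel} t} + c_{rel}}. Fm' values are
#' back-computed via \eqn{F_m' = F_m / (NPQ + 1)} and then perturbed with
#' multiplicative log-normal noise (fluorescence is strictly positive). Fm
#' and Fo are set from a configurable dark-adapted Fv/Fm.
#'
#' @param aInd,bInd Induction amplitude (NPQ units) and rate constant
#'   (min-1).
#' @param aRel,bRel,cRel Relaxation amplitude, rate constant and sustained
#'   offset.
#' @param protocol Pulse-time protocol, see [npqProtocol()].
#' @param noiseSd SD of the log-scale multiplicative noise on Fm'.
#' @param seed Integer seed.
#' @param fvfm Dark-adapted Fv/Fm used to place Fo below Fm.
#' @param Fm Dark-adapted maximal fluorescence (relative units).
#' @param leafId,instrument Metadata for the returned trace.
#' @return A \linkS4class{FluorTrace}.
#' @examples
#' tr <- generateNpqTrace(noiseSd = 0, seed = 1)
#' table(pulses(tr)$phase)
#' @export
generateNpqTrace <- function(aInd = 2.5, bInd = 0.4, aRel = 2.0,
                             bRel = 0.5, cRel = 0.4,
                             protocol = npqProtocol(), noiseSd = 0.02,
                             seed = 1L, fvfm = 0.8, Fm = 1,
                             leafId = "leaf1", instrument = "chamber") {
  if (any(c(aInd, bInd, aRel, bRel, cRel) < 0))
    stop("all kinetic parameters must be non-negative")
  for (ph in c("induction", "relaxation")) {
    tt <- protocol[[ph]]
    if (is.null(tt) || !length(tt) || any(diff(tt) <= 0))
      stop(sprintf("protocol %s pulse times must be non-empty and strictly increasing", ph))
  }
  npqInd <- aInd * (1 - exp(-bInd * protocol$induction))
  npqRel <- aRel * exp(-bRel * protocol$relaxation) + cRel
  npq <- c(npqInd, npqRel)
  fmp <- Fm / (npq + 1)
  n <- length(fmp)
  .withSeed(childSeed(seed, "npq", leafId, instrument), {
    fmp <- fmp * exp(rnorm(n, 0, noiseSd))
  })
  pulsesDf <- data.frame(
    phase = rep(c("induction", "relaxation"),
                c(length(protocol$induction), length(protocol$relaxation))),
    t = c(protocol$induction, protocol$relaxation),
    Fm_prime = fmp
  )
  fluorTrace(pulsesDf, FmDark = Fm, Fo = Fm * (1 - fvfm),
             leafId = leafId, instrument = instrument)
}
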