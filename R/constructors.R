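## User-facing constructors, accessors and show() methods.

#' Construct kinetic constants (25 degrees C defaults)
#'
#' Defaults are the community-standard Rubisco constants at 25 degrees C
#' used by mainstream A/ci fitting tools: gammastar = 42.75 umol mol-1,
#' Kc = 404.9 umol mol-1, Ko = 278.4 mmol mol-1, O = 210 mmol mol-1, which
#' imply Km = Kc (1 + O/Ko) of roughly 710 umol mol-1. All overridable.
#'
#' @param gammastar,Kc,Ko,O,leafTemp See \linkS4class{KineticConstants}.
#' @return A \linkS4class{KineticConstants} object.
#' @examples
#' kc <- kineticConstants()
#' kmOf(kc)
#' @export
kineticConstants <- function(gammastar = 42.75, Kc = 404.9, Ko = 278.4,
                             O = 210, leafTemp = 25) {
  new("KineticConstants", gammastar = gammastar, Kc = Kc, Ko = Ko, O = O,
      leafTemp = leafTemp)
}

#' @rdname accessors
#' @param x An object of the documented classes.
#' @export
setMethod("kmOf", "KineticConstants", function(x) x@Kc * (1 + x@O / x@Ko))

setMethod("show", "KineticConstants", function(object) {
  cat("KineticConstants @", object@leafTemp, "C\n")
  cat(sprintf("  gammastar = %.2f umol mol-1, Kc = %.1f umol mol-1\n",
              object@gammastar, object@Kc))
  cat(sprintf("  Ko = %.1f mmol mol-1, O = %.0f mmol mol-1 (Km = %.1f umol mol-1)\n",
              object@Ko, object@O, kmOf(object)))
})

#' Construct an A/ci curve
#'
#' @param points data.frame with columns \code{co2_set}, \code{ci},
#'   \code{A}, \code{gs}, rows in measurement order.
#' @param species,treatment,timeOfDay,replicateId Metadata scalars.
#' @return An \linkS4class{ACiCurve}.
#' @examples
#' pts <- data.frame(co2_set = c(400, 700), ci = c(280, 490),
#'                   A = c(20, 28), gs = c(0.3, 0.28))
#' aciCurve(pts, species = "tomato")
#' @export
aciCurve <- function(points, species = "tomato", treatment = "attached",
                     timeOfDay = "AM", replicateId = "r1") {
  new("ACiCurve", species = species, treatment = treatment,
      timeOfDay = timeOfDay, replicateId = replicateId,
      points = as.data.frame(points))
}

#' @rdname accessors
#' @export
setMethod("aciPoints", "ACiCurve", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("speciesOf", "ACiCurve", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("treatmentOf", "ACiCurve", function(x) x@treatment)

#' @rdname accessors
#' @export
setMethod("timeOfDayOf", "ACiCurve", function(x) x@timeOfDay)

#' @rdname accessors
#' @export
setMethod("replicateIdOf", "ACiCurve", function(x) x@replicateId)

setMethod("show", "ACiCurve", function(object) {
  pts <- object@points
  cat(sprintf("ACiCurve: %s %s %s replicate %s\n", object@species,
              object@treatment, object@timeOfDay, object@replicateId))
  cat(sprintf("  %d points, ci in [%.1f, %.1f] umol mol-1, A in [%.2f, %.2f] umol m-2 s-1\n",
              nrow(pts), min(pts$ci), max(pts$ci), min(pts$A), max(pts$A)))
})

#' Construct a fluorescence pulse trace
#'
#' @param pulses data.frame with columns \code{phase} ("induction" /
#'   "relaxation"), \code{t} (minutes since phase start) and
#'   \code{Fm_prime}.
#' @param FmDark,Fo Dark-adapted maximal and minimal fluorescence.
#' @param leafId,instrument Metadata scalars. Traces from different
#'   instruments are analysed independently.
#' @return A \linkS4class{FluorTrace}.
#' @export
fluorTrace <- function(pulses, FmDark, Fo, leafId = "leaf1",
                       instrument = "chamber") {
  new("FluorTrace", leafId = leafId, instrument = instrument,
      FmDark = FmDark, Fo = Fo, pulses = as.data.frame(pulses))
}

#' @rdname accessors
#' @export
setMethod("pulses", "FluorTrace", function(x) x@pulses)

setMethod("show", "FluorTrace", function(object) {
  p <- object@pulses
  cat(sprintf("FluorTrace: leaf %s (%s instrument)\n", object@leafId,
              object@instrument))
  cat(sprintf("  Fm = %.3g, Fo = %.3g (Fv/Fm = %.3f)\n", object@FmDark,
              object@Fo, (object@FmDark - object@Fo) / object@FmDark))
  cat(sprintf("  %d induction + %d relaxation pulses\n",
              sum(p$phase == "induction"), sum(p$phase == "relaxation")))
})

#' @rdname accessors
#' @export
setMethod("fitCoefs", "FvCBFit", function(x)
  c(Vcmax = x@Vcmax, Jmax = x@Jmax, Rd = x@Rd,
    transition_ci = x@transitionCi, sse = x@sse))

#' @rdname accessors
#' @export
setMethod("fitCoefs", "C4Fit", function(x)
  c(Vpmax = x@Vpmax, Kp = x@Kp, Rd_slope = x@RdSlope, Amax = x@Amax,
    phi = x@phi, theta = x@theta, offset = x@offset, sse = x@sse))

#' @rdname accessors
#' @export
setMethod("fitCoefs", "NPQFit", function(x)
  c(a = x@a, b = x@b, c = x@c, rmse = x@rmse))

#' @rdname accessors
#' @export
setMethod("isConverged", "FvCBFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "C4Fit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "NPQFit", function(x) x@converged)

setMethod("show", "FvCBFit", function(object) {
  if (!object@converged) {
    cat("FvCBFit: FAILED fit (degenerate input)\n")
    return(invisible(NULL))
  }
  cat(sprintf("FvCBFit: Vcmax = %.2f, Jmax = %.2f, Rd = %.2f umol m-2 s-1\n",
              object@Vcmax, object@Jmax, object@Rd))
  cat(sprintf("  transition ci = %.1f umol mol-1, SSE = %.4g (%d points)\n",
              object@transitionCi, object@sse, object@nPoints))
})

setMethod("show", "C4Fit", function(object) {
  if (!object@converged) {
    cat("C4Fit: FAILED fit\n")
    return(invisible(NULL))
  }
  cat(sprintf("C4Fit: Vpmax = %.2f (Kp = %.0f fixed), Amax = %.2f umol m-2 s-1\n",
              object@Vpmax, object@Kp, object@Amax))
  cat(sprintf("  phi = %.3f, theta = %.3f%s, offset = %.2f, SSE = %.4g\n",
              object@phi, object@theta,
              if (isTRUE(object@thetaPinned)) " (pinned at bound)" else "",
              object@offset, object@sse))
})

setMethod("show", "NPQFit", function(object) {
  if (!object@converged) {
    cat(sprintf("NPQFit (%s): FAILED fit\n", object@phase))
    return(invisible(NULL))
  }
  if (object@phase == "induction") {
    cat(sprintf("NPQFit (induction): a = %.3f, b = %.3f min-1, RMSE = %.3g\n",
                object@a, object@b, object@rmse))
  } else {
    cat(sprintf("NPQFit (relaxation): a = %.3f, b = %.3f min-1, c = %.3f, RMSE = %.3g\n",
                object@a, object@b, object@c, object@rmse))
  }
})

#' Construct a spectra collection
#'
#' @param reflectance Numeric matrix, wavelengths in rows, samples in
#'   columns; values in [0, 1].
#' @param wavelength Numeric vector of wavelengths (nm), strictly
#'   increasing, length nrow(reflectance).
#' @param sampleData data.frame / DataFrame with one row per column of
#'   \code{reflectance}; must carry \code{leaf_id}, \code{treatment},
#'   \code{time_of_day}.
#' @return A \linkS4class{SpectraSet}.
#' @export
spectraSet <- function(reflectance, wavelength, sampleData) {
  se <- SummarizedExperiment(
    assays = list(reflectance = as.matrix(reflectance)),
    rowData = S4Vectors::DataFrame(wavelength = wavelength),
    colData = S4Vectors::DataFrame(sampleData)
  )
  new("SpectraSet", se)
}

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectraSet", function(x) rowData(x)$wavelength)

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cd <- colData(object)
  cat(sprintf("SpectraSet: %d wavelengths (%g-%g nm), %d spectra\n",
              length(wl), min(wl), max(wl), ncol(object)))
  cat(sprintf("  %d leaves, treatments: %s; times: %s\n",
              length(unique(cd$leaf_id)),
              paste(sort(unique(cd$treatment)), collapse = "/"),
              paste(sort(unique(cd$time_of_day)), collapse = "/")))
})

#' Construct an effect specification
#'
#' @param baseline,treatmentDelta,timeDelta,interactionDelta,noiseSd See
#'   \linkS4class{EffectSpec}.
#' @return An \linkS4class{EffectSpec}.
#' @examples
#' effectSpec(baseline = -0.237, treatmentDelta = 0.044, noiseSd = 0.02)
#' @export
effectSpec <- function(baseline = 0, treatmentDelta = 0, timeDelta = 0,
                       interactionDelta = 0, noiseSd = 0) {
  new("EffectSpec", baseline = baseline, treatmentDelta = treatmentDelta,
      timeDelta = timeDelta, interactionDelta = interactionDelta,
      noiseSd = noiseSd)
}

setMethod("show", "EffectSpec", function(object) {
  cat(sprintf(
    "EffectSpec: baseline %.4g, treatment %+.4g, time %+.4g, interaction %+.4g, noise sd %.4g\n",
    object@baseline, object@treatmentDelta, object@timeDelta,
    object@interactionDelta, object@noiseSd))
})

#' Construct a synthetic experiment design
#'
#' Default replicate counts per treatment follow the experimental design the
#' generator emulates: 10 tomato, 8 barley, 12 maize plants per treatment.
#'
#' @param species One of "tomato", "barley", "maize".
#' @param nRepsPerTreatment Replicates per treatment (>= 2); defaults per
#'   species as above.
#' @param seed Integer seed; fully determines all generated randomness.
#' @param effects Named list of \linkS4class{EffectSpec}, one per trait.
#' @return An \linkS4class{ExperimentDesign}.
#' @examples
#' d <- experimentDesign("barley", seed = 1,
#'                       effects = list(water_potential = effectSpec(-0.237, 0.044, noiseSd = 0.02)))
#' @export
experimentDesign <- function(species = c("tomato", "barley", "maize"),
                             nRepsPerTreatment = NULL, seed = 1L,
                             effects = list()) {
  species <- match.arg(species)
  if (is.null(nRepsPerTreatment))
    nRepsPerTreatment <- defaultReps(species)
  new("ExperimentDesign", species = species,
      nRepsPerTreatment = as.integer(nRepsPerTreatment),
      treatments = c("attached", "excised"), times = c("AM", "PM"),
      seed = as.integer(seed), effects = effects)
}

#' @rdname accessors
#' @export
setMethod("speciesOf", "ExperimentDesign", function(x) x@species)

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign: %s, %d replicates/treatment, seed %d\n",
              object@species, object@nRepsPerTreatment, object@seed))
  if (length(object@effects))
    cat("  traits:", paste(names(object@effects), collapse = ", "), "\n")
})

#' Default replicate count per treatment for a species
#'
#' @param species One of "tomato", "barley", "maize".
#' @return Integer replicate count (10, 8 or 12).
#' @export
defaultReps <- function(species = c("tomato", "barley", "maize")) {
  species <- match.arg(species)
  c(tomato = 10L, barley = 8L, maize = 12L)[[species]]
}
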