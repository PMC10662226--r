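## S4 class definitions and validity methods for the package's central
## data containers.

#' Rubisco kinetic constants at the measurement temperature
#'
#' Container for the Rubisco/RuBP-regeneration kinetic constants used by the
#' FvCB forward model and the bilinear fit. All measurements in the targeted
#' experimental design are taken at a single block temperature (25 degrees C),
#' so the constants are fixed scalars with no temperature response. The
#' effective Michaelis-Menten constant is derived as
#' \code{Km = Kc * (1 + O / Ko)}, never stored.
#'
#' @slot gammastar CO2 compensation point in the absence of day respiration
#'   (umol mol-1).
#' @slot Kc Michaelis constant of Rubisco for CO2 (umol mol-1).
#' @slot Ko Michaelis constant of Rubisco for O2 (mmol mol-1).
#' @slot O Oxygen concentration (mmol mol-1).
#' @slot leafTemp Leaf/block temperature the constants refer to (degrees C).
#'
#' @seealso [kineticConstants()], [kmOf()]
#' @exportClass KineticConstants
setClass("KineticConstants",
  representation(
    gammastar = "numeric",
    Kc = "numeric",
    Ko = "numeric",
    O = "numeric",
    leafTemp = "numeric"
  )
)

setValidity("KineticConstants", function(object) {
  v <- c(gammastar = object@gammastar, Kc = object@Kc,
         Ko = object@Ko, O = object@O)
  if (any(!is.finite(v)) || any(v <= 0))
    return("gammastar, Kc, Ko and O must all be finite and positive")
  if (length(object@leafTemp) != 1L || !is.finite(object@leafTemp))
    return("leafTemp must be a single finite number")
  TRUE
})

#' A/ci response curve for one replicate leaf
#'
#' One replicate's CO2-response measurement series: net assimilation (A),
#' intercellular CO2 (ci) and stomatal conductance (gs) at each CO2
#' setpoint, in measurement order, with species / treatment / time-of-day
#' metadata.
#'
#' @slot species Character scalar, one of "tomato", "barley", "maize".
#' @slot treatment Character scalar, "attached" or "excised".
#' @slot timeOfDay Character scalar, "AM" or "PM".
#' @slot replicateId Character scalar identifying the replicate plant/leaf.
#' @slot points data.frame with columns \code{co2_set}, \code{ci}, \code{A},
#'   \code{gs}, one row per logged point, in measurement order.
#'
#' @seealso [aciCurve()], [aciPoints()]
#' @exportClass ACiCurve
setClass("ACiCurve",
  representation(
    species = "character",
    treatment = "character",
    timeOfDay = "character",
    replicateId = "character",
    points = "data.frame"
  )
)

setValidity("ACiCurve", function(object) {
  pts <- object@points
  need <- c("co2_set", "ci", "A", "gs")
  if (!all(need %in% names(pts)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (nrow(pts) == 0L) return("points must contain at least one row")
  if (any(!is.finite(pts$ci)) || any(pts$ci < 0))
    return("ci must be finite and non-negative for all points")
  if (any(!is.finite(pts$A)))
    return("A must be finite for all points")
  TRUE
})

#' Fitted C3 (FvCB) capacity parameters
#'
#' Result of the bilinear FvCB fit: maximum Rubisco carboxylation rate
#' (Vcmax), maximum electron transport rate for RuBP regeneration (Jmax),
#' day respiration (Rd) and the ci at which limitation transitions from
#' Rubisco to RuBP regeneration.
#'
#' @slot Vcmax,Jmax,Rd Fitted capacities and day respiration
#'   (umol m-2 s-1).
#' @slot transitionCi Transition ci (umol mol-1), midpoint between the two
#'   points straddling the selected split.
#' @slot sse Full-curve sum of squared errors against min(Ac, Aj) - Rd.
#' @slot nPoints Number of points used.
#' @slot converged Logical; FALSE flags a degenerate/failed fit (estimates
#'   are NA).
#'
#' @seealso [fitFvcbBilinear()]
#' @exportClass FvCBFit
setClass("FvCBFit",
  representation(
    Vcmax = "numeric", Jmax = "numeric", Rd = "numeric",
    transitionCi = "numeric", sse = "numeric",
    nPoints = "integer", converged = "logical"
  )
)

setValidity("FvCBFit", function(object) {
  if (object@converged) {
    if (!is.finite(object@Vcmax) || object@Vcmax <= 0)
      return("converged fit requires Vcmax > 0")
    if (!is.finite(object@Jmax) || object@Jmax <= 0)
      return("converged fit requires Jmax > 0")
  }
  TRUE
})

#' Fitted C4 capacity parameters
#'
#' Combined result of the PEPc initial-slope fit (Vpmax with fixed Kp) and
#' the four-parameter non-rectangular hyperbola fit whose horizontal
#' asymptote estimates CO2- and light-saturated assimilation (Amax).
#'
#' @slot Vpmax Maximum PEPc carboxylation rate (umol m-2 s-1).
#' @slot Kp PEP carboxylase Michaelis constant for CO2 held fixed during the
#'   initial-slope fit (umol mol-1).
#' @slot RdSlope Day respiration estimated by the initial-slope fit
#'   (umol m-2 s-1).
#' @slot Amax Horizontal asymptote of the fitted hyperbola, Asat + offset
#'   (umol m-2 s-1).
#' @slot phi Initial slope of the hyperbola (mol mol-1).
#' @slot theta Curvature parameter in (0, 1].
#' @slot offset Vertical offset of the hyperbola (umol m-2 s-1).
#' @slot sse Sum of squared errors (slope-subset SSE + hyperbola SSE).
#' @slot thetaPinned Logical; TRUE when theta converged onto a bound.
#' @slot converged Logical; FALSE flags a failed fit.
#'
#' @seealso [fitVpmax()], [fitNrhAmax()]
#' @exportClass C4Fit
setClass("C4Fit",
  representation(
    Vpmax = "numeric", Kp = "numeric", RdSlope = "numeric",
    Amax = "numeric", phi = "numeric", theta = "numeric",
    offset = "numeric", sse = "numeric",
    thetaPinned = "logical", converged = "logical"
  )
)

setValidity("C4Fit", function(object) {
  if (object@converged) {
    if (is.finite(object@Vpmax) && object@Vpmax <= 0)
      return("Vpmax must be positive")
    if (is.finite(object@theta) && (object@theta <= 0 || object@theta > 1))
      return("theta must lie in (0, 1]")
  }
  TRUE
})

#' Pulse-amplitude fluorescence trace for one leaf
#'
#' Dark-adapted references (Fm, Fo) plus the ordered series of saturating
#' pulses, each yielding a light-adapted maximal fluorescence Fm'. Pulses are
#' split into an induction phase (actinic light on) and a relaxation phase
#' (light off, time re-zeroed at light-off).
#'
#' @slot leafId Character scalar.
#' @slot instrument Character scalar; traces from different fluorometers are
#'   analysed independently and never pooled.
#' @slot FmDark Dark-adapted maximal fluorescence Fm (relative units, > 0).
#' @slot Fo Dark-adapted minimal fluorescence (relative units, 0 < Fo < Fm).
#' @slot pulses data.frame with columns \code{phase} ("induction" or
#'   "relaxation"), \code{t} (minutes since phase start) and
#'   \code{Fm_prime} (> 0).
#'
#' @seealso [fluorTrace()], [generateNpqTrace()]
#' @exportClass FluorTrace
setClass("FluorTrace",
  representation(
    leafId = "character",
    instrument = "character",
    FmDark = "numeric",
    Fo = "numeric",
    pulses = "data.frame"
  )
)

setValidity("FluorTrace", function(object) {
  if (!is.finite(object@FmDark) || object@FmDark <= 0)
    return("FmDark must be positive")
  if (!is.finite(object@Fo) || object@Fo <= 0 || object@Fo >= object@FmDark)
    return("Fo must satisfy 0 < Fo < FmDark")
  p <- object@pulses
  need <- c("phase", "t", "Fm_prime")
  if (!all(need %in% names(p)))
    return(paste("pulses must have columns", paste(need, collapse = ", ")))
  if (!all(p$phase %in% c("induction", "relaxation")))
    return("phase must be 'induction' or 'relaxation'")
  if (any(p$Fm_prime <= 0)) return("Fm_prime must be positive")
  for (ph in unique(p$phase)) {
    tt <- p$t[p$phase == ph]
    if (any(diff(tt) <= 0))
      return(sprintf("pulse times must be strictly increasing within the %s phase", ph))
  }
  TRUE
})

#' Fitted NPQ kinetic parameters for one phase
#'
#' Exponential induction (NPQ = a (1 - e^(-b t))) or relaxation
#' (NPQ = a e^(-b t) + c) fit. For induction fits \code{c} is \code{NA} by
#' construction (the model has no offset).
#'
#' @slot phase "induction" or "relaxation".
#' @slot a Amplitude (NPQ units).
#' @slot b Rate constant (min-1), non-negative.
#' @slot c Offset for sustained quenching (NPQ units; NA for induction).
#' @slot rmse Root-mean-square residual of the fit.
#' @slot converged Logical.
#'
#' @seealso [fitInduction()], [fitRelaxation()]
#' @exportClass NPQFit
setClass("NPQFit",
  representation(
    phase = "character", a = "numeric", b = "numeric", c = "numeric",
    rmse = "numeric", converged = "logical"
  )
)

setValidity("NPQFit", function(object) {
  if (!object@phase %in% c("induction", "relaxation"))
    return("phase must be 'induction' or 'relaxation'")
  if (object@phase == "induction" && !is.na(object@c))
    return("induction fits carry no offset c")
  if (object@converged && (!is.finite(object@b) || object@b < 0))
    return("rate constant b must be non-negative")
  TRUE
})

#' Collection of leaf reflectance spectra on a common wavelength grid
#'
#' Extends \linkS4class{SummarizedExperiment}: the "reflectance" assay is a
#' wavelength x sample matrix, \code{rowData} carries the wavelength grid
#' (nm, strictly increasing) and \code{colData} carries \code{leaf_id},
#' \code{species}, \code{treatment}, \code{time_of_day} and (optionally)
#' \code{technical_rep} labels.
#'
#' @seealso [spectraSet()], [generateSpectra()], [averageTechnicalReps()],
#'   [spectraWideAnova()]
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    return("SpectraSet requires a 'reflectance' assay")
  wl <- rowData(object)$wavelength
  if (is.null(wl)) return("rowData must carry a 'wavelength' column")
  if (any(!is.finite(wl)) || any(diff(wl) <= 0))
    return("wavelength grid must be finite and strictly increasing")
  need <- c("leaf_id", "treatment", "time_of_day")
  if (!all(need %in% names(colData(object))))
    return(paste("colData must carry", paste(need, collapse = ", ")))
  refl <- assay(object, "reflectance")
  if (length(refl) && (any(!is.finite(refl)) || any(refl < 0) || any(refl > 1)))
    return("reflectance values must be finite and within [0, 1]")
  TRUE
})

#' Additive effect specification for one synthetic trait
#'
#' Encodes the additive treatment / time-of-day / interaction effect
#' structure assumed by the two-way repeated-measures ANOVA:
#' value = baseline + treatment_delta x 1[excised] + time_delta x 1[PM] +
#' interaction_delta x 1[excised & PM] + Gaussian noise.
#'
#' @slot baseline Trait value for an attached leaf in the morning (trait
#'   units).
#' @slot treatmentDelta Additive shift for excised leaves.
#' @slot timeDelta Additive shift in the afternoon.
#' @slot interactionDelta Extra shift for excised leaves in the afternoon.
#' @slot noiseSd Gaussian noise standard deviation (>= 0).
#'
#' @seealso [effectSpec()], [generateTraitTable()]
#' @exportClass EffectSpec
setClass("EffectSpec",
  representation(
    baseline = "numeric", treatmentDelta = "numeric",
    timeDelta = "numeric", interactionDelta = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("EffectSpec", function(object) {
  v <- c(object@baseline, object@treatmentDelta, object@timeDelta,
         object@interactionDelta, object@noiseSd)
  if (length(v) != 5L || any(!is.finite(v)))
    return("all EffectSpec fields must be single finite numbers")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})

#' Synthetic experiment design
#'
#' The species x treatment x time-of-day x replicate layout of the
#' experiment, the seed that determines every generated value, and the
#' per-trait effect specifications.
#'
#' @slot species One of "tomato", "barley", "maize".
#' @slot nRepsPerTreatment Integer >= 2; replicate plants per treatment.
#' @slot treatments Fixed pair c("attached", "excised").
#' @slot times Fixed pair c("AM", "PM").
#' @slot seed Integer seed; fully determines all generated randomness.
#' @slot effects Named list of \linkS4class{EffectSpec}, one per trait.
#'
#' @seealso [experimentDesign()]
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(
    species = "character",
    nRepsPerTreatment = "integer",
    treatments = "character",
    times = "character",
    seed = "integer",
    effects = "list"
  )
)

setValidity("ExperimentDesign", function(object) {
  if (!object@species %in% c("tomato", "barley", "maize"))
    return("species must be one of 'tomato', 'barley', 'maize'")
  if (length(object@nRepsPerTreatment) != 1L || object@nRepsPerTreatment < 2L)
    return("nRepsPerTreatment must be a single integer >= 2")
  if (!identical(sort(object@treatments), c("attached", "excised")))
    return("treatments must be the pair attached/excised")
  if (!identical(sort(object@times), c("AM", "PM")))
    return("times must be the pair AM/PM")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  if (length(object@effects)) {
    if (is.null(names(object@effects)) || any(names(object@effects) == ""))
      return("effects must be a named list")
    ok <- vapply(object@effects, function(e) is(e, "EffectSpec"), logical(1))
    if (!all(ok)) return("all effects entries must be EffectSpec objects")
  }
  TRUE
})
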