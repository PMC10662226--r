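## Synthetic scalar trait tables with the additive treatment x time effect
## structure assumed by the repeated-measures ANOVA.

#' Default effect specifications emulating the study's qualitative findings
#'
#' A per-species registry of scalar traits with effect sizes chosen to
#' emulate the qualitative patterns the design targets: an afternoon
#' decline in net assimilation for barley and maize, a treatment effect on
#' stomatal conductance (reduced in excised leaves, about -25 percent of
#' baseline) in maize only, and a small positive excision effect on barley
#' leaf water potential (attached baseline -0.237 MPa, excised shift
#' +0.044 MPa). Noise levels are free parameters of the generator (the
#' design they emulate reports only means) and are set to plausible
#' measurement dispersions.
#'
#' @param species One of "tomato", "barley", "maize".
#' @return Named list of \linkS4class{EffectSpec} objects.
#' @export
defaultEffects <- function(species = c("tomato", "barley", "maize")) {
  species <- match.arg(species)
  switch(species,
    tomato = list(
      AN = effectSpec(baseline = 25, timeDelta = -0.5, noiseSd = 2),
      gs = effectSpec(baseline = 0.30, noiseSd = 0.04),
      water_potential = effectSpec(baseline = -0.30, noiseSd = 0.03),
      ABA = effectSpec(baseline = 40, noiseSd = 8)
    ),
    barley = list(
      AN = effectSpec(baseline = 20, timeDelta = -2, noiseSd = 2),
      gs = effectSpec(baseline = 0.25, timeDelta = -0.03, noiseSd = 0.03),
      water_potential = effectSpec(baseline = -0.237, treatmentDelta = 0.044,
                                   noiseSd = 0.02),
      ABA = effectSpec(baseline = 35, noiseSd = 7)
    ),
    maize = list(
      AN = effectSpec(baseline = 30, timeDelta = -2.5, noiseSd = 2),
      gs = effectSpec(baseline = 0.20, treatmentDelta = -0.05,
                      noiseSd = 0.025),
      water_potential = effectSpec(baseline = -0.25, noiseSd = 0.03),
      ABA = effectSpec(baseline = 30, noiseSd = 6)
    )
  )
}

#' Generate a synthetic trait table
#'
#' One row per replicate x treatment x time (or per replicate x treatment
#' when \code{withTime = FALSE}, for end-of-day traits such as leaf water
#' potential). Values follow
#' \code{baseline + treatment_delta 1[excised] + time_delta 1[PM] +
#' interaction_delta 1[excised and PM] + N(0, noise_sd)}. Replicate IDs are
#' consistent across the AM/PM rows of one plant (repeated measures), and
#' each replicate has its own random stream, so adding replicates never
#' perturbs existing rows.
#'
#' @param design An \linkS4class{ExperimentDesign} whose \code{effects}
#'   contain \code{trait}.
#' @param trait Trait name to generate.
#' @param withTime Logical; include the AM/PM within-subject factor.
#' @return data.frame with columns \code{species}, \code{trait},
#'   \code{replicate_id}, \code{treatment}, \code{time_of_day} (when
#'   \code{withTime}) and \code{value}.
#' @examples
#' d <- experimentDesign("barley", seed = 1,
#'        effects = list(water_potential = effectSpec(-0.237, 0.044, noiseSd = 0.02)))
#' head(generateTraitTable(d, "water_potential"))
#' @export
generateTraitTable <- function(design, trait, withTime = TRUE) {
  spec <- design@effects[[trait]]
  if (is.null(spec))
    stop(sprintf("unknown trait '%s': no EffectSpec in the design", trait))
  times <- if (withTime) design@times else "AM"
  rows <- list()
  for (tr in design@treatments) {
    for (r in seq_len(design@nRepsPerTreatment)) {
      repId <- sprintf("%s_%s_%02d", design@species, tr, r)
      noise <- .withSeed(childSeed(design@seed, "trait", trait, repId),
                         rnorm(length(times), 0, spec@noiseSd))
      for (j in seq_along(times)) {
        tm <- times[j]
        mu <- spec@baseline +
          spec@treatmentDelta * (tr == "excised") +
          spec@timeDelta * (tm == "PM") +
          spec@interactionDelta * (tr == "excised" && tm == "PM")
        row <- data.frame(species = design@species, trait = trait,
                          replicate_id = repId, treatment = tr,
                          value = mu + noise[j])
        if (withTime) row$time_of_day <- tm
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (withTime)
    out <- out[, c("species", "trait", "replicate_id", "treatment",
                   "time_of_day", "value")]
  out
}
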