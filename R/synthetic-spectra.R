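## Synthetic leaf reflectance spectra.

#' Parametric template for a healthy leaf reflectance spectrum
#'
#' Smooth, qualitatively realistic base curve: low visible reflectance with
#' a green-region bump near 550 nm, a logistic red-edge shoulder rising to a
#' near-infrared plateau, broad water-absorption dips centred near 1450 and
#' 1940 nm and a declining short-wave-infrared tail. Chosen for smoothness
#' and plausibility, not radiative-transfer fidelity.
#'
#' @param wavelength Wavelengths in nm, vectorised.
#' @return Reflectance in [0, 1].
#' @export
baseLeafSpectrum <- function(wavelength) {
  wl <- wavelength
  r <- 0.05 +
    0.06 * exp(-((wl - 550) / 25)^2) +                 # green bump
    0.45 / (1 + exp(-(wl - 715) / 12)) -               # red-edge shoulder
    0.18 * exp(-((wl - 1450) / 35)^2) -                # water absorption
    0.28 * exp(-((wl - 1940) / 45)^2) -                # water absorption
    0.10 * exp(-((wl - 2500) / 120)^2)                 # SWIR decline
  r <- r - pmax(wl - 1300, 0) / 1200 * 0.10            # gentle SWIR slope
  pmin(pmax(r, 0), 1)
}

#' Default 1 nm wavelength grid
#'
#' @return Integer grid 350..2500 nm (2151 points).
#' @export
defaultWavelengthGrid <- function() 350:2500

#' Generate a synthetic spectra collection
#'
#' Each leaf in the design (both treatments, both time points) receives
#' \code{nTechnical} technical-replicate spectra: the parametric base leaf
#' curve, plus treatment-dependent Gaussian bumps (applied to excised
#' leaves only) described by \code{effectBands}, plus per-leaf and
#' per-technical-replicate Gaussian noise. All reflectance is clipped to
#' [0, 1]. Random streams are split per leaf, so adding replicates never
#' perturbs existing spectra.
#'
#' @param design An \linkS4class{ExperimentDesign}.
#' @param effectBands \code{NULL}, or a data.frame with columns
#'   \code{center} (nm), \code{width} (nm; Gaussian SD) and
#'   \code{amplitude} (reflectance units, signed). Centres must lie on the
#'   grid.
#' @param nTechnical Technical replicates per leaf (>= 1; the measurement
#'   protocol uses 3).
#' @param noiseSd Per-wavelength Gaussian noise SD.
#' @param seed Integer seed; defaults to the design's seed.
#' @param wavelength Wavelength grid (nm), strictly increasing.
#' @param leafSd SD of the smooth per-leaf brightness offset (a single
#'   scalar per leaf, emulating leaf-to-leaf albedo variation).
#' @return A \linkS4class{SpectraSet} with one column per
#'   leaf x time x technical replicate.
#' @export
generateSpectra <- function(design, effectBands = NULL, nTechnical = 3,
                            noiseSd = 0.01, seed = design@seed,
                            wavelength = defaultWavelengthGrid(),
                            leafSd = 0.005) {
  stopifnot(nTechnical >= 1)
  if (!is.null(effectBands)) {
    effectBands <- as.data.frame(effectBands)
    stopifnot(all(c("center", "width", "amplitude") %in% names(effectBands)))
    if (any(effectBands$center < min(wavelength) |
            effectBands$center > max(wavelength)))
      stop("effect band centers must lie within the wavelength grid")
  }
  base <- baseLeafSpectrum(wavelength)
  bump <- numeric(length(wavelength))
  if (!is.null(effectBands) && nrow(effectBands)) {
    for (i in seq_len(nrow(effectBands))) {
      bump <- bump + effectBands$amplitude[i] *
        exp(-((wavelength - effectBands$center[i]) /
                effectBands$width[i])^2 / 2)
    }
  }
  nW <- length(wavelength)
  cols <- list()
  meta <- list()
  for (tr in design@treatments) {
    for (r in seq_len(design@nRepsPerTreatment)) {
      leafId <- sprintf("%s_%s_%02d", design@species, tr, r)
      leafOffset <- .withSeed(childSeed(seed, "spectra_leaf", leafId),
                              rnorm(1, 0, leafSd))
      for (tm in design@times) {
        for (k in seq_len(nTechnical)) {
          noise <- .withSeed(
            childSeed(seed, "spectra", leafId, tm, k),
            rnorm(nW, 0, noiseSd))
          r0 <- base + leafOffset + noise
          if (tr == "excised") r0 <- r0 + bump
          cols[[length(cols) + 1L]] <- pmin(pmax(r0, 0), 1)
          meta[[length(meta) + 1L]] <- data.frame(
            leaf_id = leafId, species = design@species, treatment = tr,
            time_of_day = tm, technical_rep = k)
        }
      }
    }
  }
  refl <- do.call(cbind, cols)
  cd <- do.call(rbind, meta)
  colnames(refl) <- sprintf("%s_%s_t%d", cd$leaf_id, cd$time_of_day,
                            cd$technical_rep)
  rownames(cd) <- colnames(refl)
  spectraSet(refl, wavelength, cd)
}
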