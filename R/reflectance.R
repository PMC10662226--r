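## Reflectance analysis: technical-replicate averaging, index computation,
## spectra-wide per-wavelength ANOVA with Bonferroni control.

#' Average technical replicates within each leaf x time point
#'
#' Element-wise arithmetic mean of the technical-replicate spectra of each
#' leaf at each time point, matching the measurement protocol (three
#' technical scans averaged per leaf before analysis).
#'
#' @param spectra A \linkS4class{SpectraSet}.
#' @return A \linkS4class{SpectraSet} with one column per leaf x time.
#' @export
averageTechnicalReps <- function(spectra) {
  cd <- as.data.frame(colData(spectra))
  key <- interaction(cd$leaf_id, cd$time_of_day, drop = TRUE)
  refl <- assay(spectra, "reflectance")
  groups <- split(seq_len(ncol(refl)), key)
  avg <- vapply(groups, function(idx) rowMeans(refl[, idx, drop = FALSE]),
                numeric(nrow(refl)))
  first <- vapply(groups, `[`, integer(1), 1L)
  meta <- cd[first, setdiff(names(cd), "technical_rep"), drop = FALSE]
  rownames(meta) <- colnames(avg) <- sprintf("%s_%s", meta$leaf_id,
                                             meta$time_of_day)
  spectraSet(avg, wavelengths(spectra), meta)
}

#' Default reflectance index registry
#'
#' Five literature-standard indices: Datt (total chlorophyll proxy), MSI
#' (moisture stress, inverse water-content proxy), NDVI, PRI and WI (water
#' index). Each definition records the bands it references (nearest grid
#' point lookup) and an expression over them; the registry is fully
#' overridable, and custom definitions can be supplied in the same form.
#'
#' @return Named list of index definitions; each has \code{name},
#'   \code{bands} (named numeric vector, nm) and \code{fun} (a function of
#'   a band-lookup function \code{R}).
#' @export
indexRegistry <- function() {
  list(
    Datt = list(name = "Datt", bands = c(850, 710, 680),
                fun = function(R) (R(850) - R(710)) / (R(850) - R(680))),
    MSI = list(name = "MSI", bands = c(1599, 819),
               fun = function(R) R(1599) / R(819)),
    NDVI = list(name = "NDVI", bands = c(800, 680),
                fun = function(R) (R(800) - R(680)) / (R(800) + R(680))),
    PRI = list(name = "PRI", bands = c(531, 570),
               fun = function(R) (R(531) - R(570)) / (R(531) + R(570))),
    WI = list(name = "WI", bands = c(900, 970),
              fun = function(R) R(900) / R(970))
  )
}

#' Compute one reflectance index for one spectrum
#'
#' Band reflectances are resolved by nearest-grid-point lookup. A zero (or
#' non-finite) denominator yields \code{NA} with a warning, never a silent
#' infinity.
#'
#' @param reflectance Numeric reflectance vector.
#' @param wavelength Matching wavelength grid (nm).
#' @param definition One entry of [indexRegistry()] (or a custom definition
#'   of the same shape), or the name of a registry entry.
#' @param registry Registry used to resolve \code{definition} by name.
#' @return Index value (possibly NA).
#' @examples
#' wl <- defaultWavelengthGrid()
#' computeIndex(rep(0.5, length(wl)), wl, "MSI")  # 1
#' @export
computeIndex <- function(reflectance, wavelength, definition,
                         registry = indexRegistry()) {
  if (is.character(definition)) {
    definition <- registry[[definition]]
    if (is.null(definition)) stop("unknown index name")
  }
  if (any(definition$bands < min(wavelength) |
          definition$bands > max(wavelength)))
    stop(sprintf("index %s references bands outside the wavelength grid",
                 definition$name))
  R <- function(lambda) reflectance[which.min(abs(wavelength - lambda))]
  value <- definition$fun(R)
  if (!is.finite(value)) {
    warning(sprintf("index %s undefined (zero or invalid denominator)",
                    definition$name))
    return(NA_real_)
  }
  value
}

#' Compute all registry indices for every spectrum in a set
#'
#' @param spectra A \linkS4class{SpectraSet} (typically technical-replicate
#'   averaged).
#' @param registry Index registry, see [indexRegistry()].
#' @return data.frame with one row per spectrum: the colData labels plus
#'   one column per index.
#' @export
computeIndices <- function(spectra, registry = indexRegistry()) {
  wl <- wavelengths(spectra)
  refl <- assay(spectra, "reflectance")
  out <- as.data.frame(colData(spectra))
  for (nm in names(registry)) {
    out[[nm]] <- apply(refl, 2L, computeIndex, wavelength = wl,
                       definition = registry[[nm]], registry = registry)
  }
  rownames(out) <- NULL
  out
}

#' Bonferroni family-wise significance threshold
#'
#' @param alpha Family-wise error rate target, in (0, 1).
#' @param nTests Number of tests (>= 1); for spectra-wide testing this is
#'   the number of wavelengths actually tested, never a hard-coded grid
#'   size.
#' @return alpha / nTests.
#' @examples
#' bonferroniThreshold(0.05, 2151)
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (!is.numeric(nTests) || nTests < 1)
    stop("nTests must be a positive count")
  alpha / nTests
}

#' Spectra-wide per-wavelength one-way ANOVA
#'
#' At every wavelength, a one-way ANOVA tests for differences in
#' reflectance between the grouping levels (by default the excised vs
#' attached treatments). Family-wise control uses a Bonferroni threshold of
#' alpha divided by the number of wavelengths tested; -log10(p) is reported
#' for plotting. Tests for different time points should be run separately
#' (use \code{time}).
#'
#' Spectra must be pre-averaged across technical replicates; wavelengths
#' with zero between- plus within-group variance get F = 0, p = 1 with a
#' warning.
#'
#' @param spectra A \linkS4class{SpectraSet} with one column per leaf (see
#'   [averageTechnicalReps()]).
#' @param grouping Name of the colData column defining groups.
#' @param alpha Family-wise error target.
#' @param time Optional time-of-day label to subset to before testing.
#' @return data.frame with columns \code{wavelength}, \code{F},
#'   \code{df_num}, \code{df_den}, \code{p}, \code{neglog10_p},
#'   \code{significant}.
#' @export
spectraWideAnova <- function(spectra, grouping = "treatment", alpha = 0.05,
                             time = NULL) {
  cd <- as.data.frame(colData(spectra))
  if (!is.null(cd$technical_rep) &&
      anyDuplicated(interaction(cd$leaf_id, cd$time_of_day)))
    stop("average technical replicates before spectra-wide testing")
  sel <- rep(TRUE, ncol(spectra))
  if (!is.null(time)) sel <- cd$time_of_day == time
  refl <- assay(spectra, "reflectance")[, sel, drop = FALSE]
  g <- factor(cd[[grouping]][sel])
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L))
    stop("each group must contain at least 2 leaves")
  N <- ncol(refl)
  k <- nlevels(g)
  grand <- rowMeans(refl)
  ssb <- 0
  ssw <- 0
  for (lev in levels(g)) {
    sub <- refl[, g == lev, drop = FALSE]
    m <- rowMeans(sub)
    ssb <- ssb + ncol(sub) * (m - grand)^2
    ssw <- ssw + rowSums((sub - m)^2)
  }
  dfNum <- k - 1L
  dfDen <- N - k
  F <- (ssb / dfNum) / (ssw / dfDen)
  p <- pf(F, dfNum, dfDen, lower.tail = FALSE)
  degenerate <- (ssb + ssw) < .Machine$double.eps * N
  if (any(degenerate)) {
    warning(sprintf("%d wavelength(s) with zero variance: p set to 1",
                    sum(degenerate)))
    F[degenerate] <- 0
    p[degenerate] <- 1
  }
  thr <- bonferroniThreshold(alpha, nrow(refl))
  data.frame(
    wavelength = wavelengths(spectra),
    F = F, df_num = dfNum, df_den = dfDen, p = p,
    neglog10_p = -log10(p),
    significant = p < thr
  )
}
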