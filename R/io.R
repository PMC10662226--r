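## CSV input/output. All writers use a canonical float format (10
## significant digits) so that repeated runs with the same seed are
## byte-identical.

.canonical <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]]))
      df[[nm]] <- trimws(formatC(df[[nm]], digits = 10, format = "g"))
  }
  df
}

#' Write a data.frame as canonical CSV
#'
#' Comma-separated, UTF-8, header row, no row names; doubles rendered with
#' 10 significant digits so identical runs produce byte-identical files.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCanonicalCsv <- function(df, path) {
  write.csv(.canonical(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a list of A/ci curves to/from the long gas-exchange table
#'
#' The long format has columns \code{species}, \code{treatment},
#' \code{time}, \code{replicate}, \code{co2_set}, \code{ci}, \code{A},
#' \code{gs}, one row per logged point.
#'
#' @param curves List of \linkS4class{ACiCurve} objects.
#' @return data.frame in long format.
#' @export
aciCurvesToTable <- function(curves) {
  out <- lapply(curves, function(cv) {
    pts <- aciPoints(cv)
    data.frame(species = speciesOf(cv), treatment = treatmentOf(cv),
               time = timeOfDayOf(cv), replicate = replicateIdOf(cv),
               co2_set = pts$co2_set, ci = pts$ci, A = pts$A, gs = pts$gs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname aciCurvesToTable
#' @param table Long-format gas-exchange data.frame.
#' @return For \code{tableToAciCurves}: a list of \linkS4class{ACiCurve}.
#' @export
tableToAciCurves <- function(table) {
  key <- interaction(table$species, table$treatment, table$time,
                     table$replicate, drop = TRUE)
  lapply(split(table, key), function(tb) {
    aciCurve(tb[, c("co2_set", "ci", "A", "gs")],
             species = tb$species[1L], treatment = tb$treatment[1L],
             timeOfDay = tb$time[1L], replicateId = tb$replicate[1L])
  })
}

#' Read a gas-exchange CSV (instrument-export tolerant)
#'
#' Header lines beginning with '#' are ignored and required columns are
#' matched by name case-insensitively, so minimal instrument exports load
#' without editing.
#'
#' @param path CSV path.
#' @return data.frame with canonical lower-case column names
#'   (\code{species}, \code{treatment}, \code{time}, \code{replicate},
#'   \code{co2_set}, \code{ci}, \code{A}, \code{gs}).
#' @export
readGasExchangeCsv <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  want <- c("species", "treatment", "time", "replicate", "co2_set", "ci",
            "A", "gs")
  idx <- match(tolower(want), tolower(names(df)))
  if (anyNA(idx))
    stop("missing required column(s): ",
         paste(want[is.na(idx)], collapse = ", "))
  df <- df[, idx]
  names(df) <- want
  df
}

#' Write/read the fluorescence long CSV
#'
#' Flat long format: one row per pulse with columns \code{leaf_id},
#' \code{instrument}, \code{Fm_dark}, \code{Fo}, \code{phase},
#' \code{t_min}, \code{Fm_prime} (the dark references repeated per row).
#'
#' @param traces List of \linkS4class{FluorTrace} objects.
#' @param path CSV path.
#' @return \code{writeFluorCsv}: the path, invisibly.
#'   \code{readFluorCsv}: a list of \linkS4class{FluorTrace}.
#' @export
writeFluorCsv <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    p <- pulses(tr)
    data.frame(leaf_id = tr@leafId, instrument = tr@instrument,
               Fm_dark = tr@FmDark, Fo = tr@Fo, phase = p$phase,
               t_min = p$t, Fm_prime = p$Fm_prime)
  })
  writeCanonicalCsv(do.call(rbind, rows), path)
}

#' @rdname writeFluorCsv
#' @export
readFluorCsv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  key <- interaction(df$leaf_id, df$instrument, drop = TRUE)
  lapply(split(df, key), function(tb) {
    fluorTrace(data.frame(phase = tb$phase, t = tb$t_min,
                          Fm_prime = tb$Fm_prime),
               FmDark = tb$Fm_dark[1L], Fo = tb$Fo[1L],
               leafId = as.character(tb$leaf_id[1L]),
               instrument = as.character(tb$instrument[1L]))
  })
}

#' Write/read a spectra collection as wide CSV
#'
#' Wide format: a \code{wavelength} column plus one column per
#' leaf x time x technical replicate; sample metadata is carried in the
#' column names (\code{leafid_time_tK}) and reconstructed on read.
#'
#' @param spectra A \linkS4class{SpectraSet}.
#' @param path CSV path.
#' @return \code{writeSpectraCsv}: the path, invisibly.
#'   \code{readSpectraCsv}: a \linkS4class{SpectraSet}.
#' @export
writeSpectraCsv <- function(spectra, path) {
  refl <- assay(spectra, "reflectance")
  df <- data.frame(wavelength = wavelengths(spectra), refl,
                   check.names = FALSE)
  writeCanonicalCsv(df, path)
}

#' @rdname writeSpectraCsv
#' @export
readSpectraCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- df$wavelength
  refl <- as.matrix(df[, setdiff(names(df), "wavelength"), drop = FALSE])
  ## column names follow species_treatment_NN_time_tK
  parts <- strsplit(colnames(refl), "_")
  meta <- do.call(rbind, lapply(parts, function(p) {
    n <- length(p)
    data.frame(leaf_id = paste(p[seq_len(n - 2L)], collapse = "_"),
               species = p[1L], treatment = p[2L],
               time_of_day = p[n - 1L],
               technical_rep = as.integer(sub("^t", "", p[n])))
  }))
  rownames(meta) <- colnames(refl)
  spectraSet(refl, wl, meta)
}
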