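## End-to-end orchestration: config validation and the full
## simulate -> fit -> test -> infer pipeline with a structured run report.

.pipelineStages <- c("simulate", "fit_aci", "fit_npq", "spectra", "infer")

.configDefaults <- function() {
  list(
    species = c("tomato", "barley", "maize"),
    seed = 1L,
    n_reps = NULL,              # per-species list or single integer
    alpha = 0.05,
    stages = .pipelineStages,
    out_dir = "leafphys_run",
    generate = TRUE,
    paths = NULL,
    noise = list(aci_sd = 0.3, npq_sd = 0.02, spectra_sd = 0.01),
    constants = list(gammastar = 42.75, Kc = 404.9, Ko = 278.4, O = 210),
    c4 = list(ci_cutoff = 100, Kp = 80),
    n_technical = 3L,
    spectra_effect_bands = NULL,
    effects = NULL,             # per-species per-trait overrides
    no_time_traits = c("water_potential", "ABA"),
    log_level = "info"
  )
}

#' Validate a pipeline configuration
#'
#' Parses a YAML file (or takes a list), fills documented defaults, and
#' checks every invariant, reporting the complete list of violations at
#' once. Unknown keys are errors: typos never pass silently.
#'
#' @param config Path to a YAML config file, or a named list.
#' @return A validated, defaulted config list of class
#'   \code{PipelineConfig}.
#' @examples
#' cfg <- validateConfig(list(species = "maize", seed = 7))
#' cfg$n_reps
#' @export
validateConfig <- function(config = list()) {
  if (is.null(config)) config <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  violations <- character(0)
  if (length(unknown))
    violations <- c(violations,
                    paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, config, keep.null = TRUE)

  if (!all(cfg$species %in% c("tomato", "barley", "maize")) ||
      !length(cfg$species))
    violations <- c(violations,
                    "species must be a non-empty subset of tomato/barley/maize")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    violations <- c(violations, "seed must be a single integer")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    violations <- c(violations, "alpha must lie in (0, 1)")
  if (!all(cfg$stages %in% .pipelineStages))
    violations <- c(violations,
                    paste("stages must be a subset of:",
                          paste(.pipelineStages, collapse = ", ")))
  if (isTRUE(cfg$generate) && !is.null(cfg$paths))
    violations <- c(violations,
                    "generate = TRUE and explicit input paths are mutually exclusive")
  if (!isTRUE(cfg$generate) && is.null(cfg$paths))
    violations <- c(violations,
                    "either generate = TRUE or input paths must be given")
  if (!is.null(cfg$n_reps)) {
    nr <- unlist(cfg$n_reps)
    if (!is.numeric(nr) || any(nr < 2) || any(nr != round(nr)))
      violations <- c(violations,
                      "n_reps must be integer(s) >= 2")
  }
  if (!is.numeric(cfg$n_technical) || cfg$n_technical < 1)
    violations <- c(violations, "n_technical must be >= 1")
  for (nm in c("aci_sd", "npq_sd", "spectra_sd")) {
    v <- cfg$noise[[nm]]
    if (!is.numeric(v) || v < 0)
      violations <- c(violations, sprintf("noise$%s must be >= 0", nm))
  }
  if (!is.null(cfg$effects)) {
    for (sp in names(cfg$effects)) {
      for (tr in names(cfg$effects[[sp]])) {
        e <- cfg$effects[[sp]][[tr]]
        ns <- e$noise_sd
        if (!is.null(ns) && (!is.numeric(ns) || ns < 0))
          violations <- c(violations,
                          sprintf("effects$%s$%s: noise_sd must be >= 0", sp, tr))
      }
    }
  }
  if (length(violations))
    stop("invalid pipeline config:\n  - ",
         paste(violations, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.repsFor <- function(cfg, species) {
  if (is.null(cfg$n_reps)) return(defaultReps(species))
  if (is.list(cfg$n_reps)) {
    r <- cfg$n_reps[[species]]
    return(if (is.null(r)) defaultReps(species) else as.integer(r))
  }
  as.integer(cfg$n_reps)
}

.effectsFor <- function(cfg, species) {
  eff <- defaultEffects(species)
  over <- cfg$effects[[species]]
  for (tr in names(over)) {
    o <- over[[tr]]
    base <- if (!is.null(eff[[tr]])) eff[[tr]] else effectSpec()
    eff[[tr]] <- effectSpec(
      baseline = o$baseline %||na% base@baseline,
      treatmentDelta = o$treatment_delta %||na% base@treatmentDelta,
      timeDelta = o$time_delta %||na% base@timeDelta,
      interactionDelta = o$interaction_delta %||na% base@interactionDelta,
      noiseSd = o$noise_sd %||na% base@noiseSd)
  }
  eff
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

.log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) the input
#' tables, fit A/ci curves (tomato/barley routed to the C3 bilinear FvCB
#' fit; maize to the C4 initial-slope + hyperbola fit), fit NPQ kinetics,
#' run the spectra-wide tests and reflectance indices, and produce the
#' inference tables. All stage outputs are canonical CSVs under
#' \code{outDir}; a JSON run report lists the manifest, per-stage record
#' counts, warnings and failed fits. A run is fully reproducible from
#' (config, seed): two runs with the same seed yield byte-identical
#' outputs.
#'
#' @param config A \code{PipelineConfig} (see [validateConfig()]), a path
#'   to a YAML config, or a list of overrides.
#' @param outDir Output directory (created if needed); defaults to the
#'   config's \code{out_dir}.
#' @param seed Seed override; defaults to the config's seed.
#' @return The run report (a list), invisibly. Also written as
#'   \code{report.json}.
#' @examples
#' \donttest{
#' cfg <- validateConfig(list(species = "maize",
#'                            n_reps = 4, out_dir = tempfile()))
#' rep <- runPipeline(cfg)
#' names(rep$manifest)
#' }
#' @export
runPipeline <- function(config = list(), outDir = NULL, seed = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else validateConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outDir)) cfg$out_dir <- outDir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  counts <- list()
  warnLog <- character(0)
  noteWarn <- function(w) warnLog <<- c(warnLog, conditionMessage(w))
  out <- function(name) file.path(cfg$out_dir, name)
  constants <- do.call(kineticConstants, cfg$constants)

  ## ---- stage: simulate -------------------------------------------------
  ## only the inputs the enabled downstream stages consume are generated
  ## (trait tables always, since inference runs on them)
  if ("simulate" %in% cfg$stages && isTRUE(cfg$generate)) {
    .log(cfg, "stage simulate: %s", paste(cfg$species, collapse = ", "))
    ## a simulate-only run is an explicit request for all the input tables
    simOnly <- identical(cfg$stages, "simulate")
    needAci <- simOnly || "fit_aci" %in% cfg$stages
    needNpq <- simOnly || "fit_npq" %in% cfg$stages
    needSpectra <- simOnly || "spectra" %in% cfg$stages
    traitRows <- list()
    curves <- list()
    traces <- list()
    spectraFiles <- character(0)
    for (sp in cfg$species) {
      design <- experimentDesign(sp, .repsFor(cfg, sp),
                                 seed = childSeed(cfg$seed, sp),
                                 effects = .effectsFor(cfg, sp))
      for (tr in names(design@effects)) {
        traitRows[[length(traitRows) + 1L]] <-
          generateTraitTable(design, tr,
                             withTime = !(tr %in% cfg$no_time_traits))
      }
      for (treat in design@treatments) {
        for (r in seq_len(design@nRepsPerTreatment)) {
          repId <- sprintf("%s_%s_%02d", sp, treat, r)
          if (needAci) {
            for (tm in design@times) {
              s <- childSeed(cfg$seed, sp, "aci", treat, tm)
              curves[[length(curves) + 1L]] <- if (sp == "maize") {
                generateAciC4(noiseSd = cfg$noise$aci_sd, seed = s,
                              species = sp, treatment = treat,
                              timeOfDay = tm, replicateId = repId)
              } else {
                generateAciC3(noiseSd = cfg$noise$aci_sd, seed = s,
                              species = sp, treatment = treat,
                              timeOfDay = tm, replicateId = repId)
              }
            }
          }
          if (needNpq) {
            ## per-leaf dark-adapted Fv/Fm varies around 0.8 (healthy leaves)
            fvfmLeaf <- 0.8 + .withSeed(childSeed(cfg$seed, sp, "fvfm", repId),
                                        rnorm(1, 0, 0.01))
            traces[[length(traces) + 1L]] <-
              generateNpqTrace(noiseSd = cfg$noise$npq_sd,
                               seed = childSeed(cfg$seed, sp, "npq", treat),
                               fvfm = min(max(fvfmLeaf, 0.5), 0.87),
                               leafId = repId, instrument = "chamber")
          }
        }
      }
      if (needSpectra) {
        ss <- generateSpectra(design, effectBands = cfg$spectra_effect_bands,
                              nTechnical = cfg$n_technical,
                              noiseSd = cfg$noise$spectra_sd,
                              seed = childSeed(cfg$seed, sp, "spectra"))
        f <- out(sprintf("spectra_%s.csv", sp))
        writeSpectraCsv(ss, f)
        spectraFiles <- c(spectraFiles, f)
      }
    }
    traits <- do.call(rbind, lapply(traitRows, function(x) {
      if (!"time_of_day" %in% names(x)) x$time_of_day <- NA_character_
      x[, c("species", "trait", "replicate_id", "treatment", "time_of_day",
            "value")]
    }))
    writeCanonicalCsv(traits, out("traits.csv"))
    manifest <- c(manifest, out("traits.csv"))
    if (needAci) {
      writeCanonicalCsv(aciCurvesToTable(curves), out("gas_exchange.csv"))
      manifest <- c(manifest, out("gas_exchange.csv"))
    }
    if (needNpq) {
      writeFluorCsv(traces, out("fluorescence.csv"))
      manifest <- c(manifest, out("fluorescence.csv"))
    }
    manifest <- c(manifest, spectraFiles)
    counts$simulate <- list(trait_rows = nrow(traits),
                            curves = length(curves),
                            traces = length(traces),
                            spectra_files = length(spectraFiles))
  }

  gasPath <- if (isTRUE(cfg$generate)) out("gas_exchange.csv") else cfg$paths$gas
  fluorPath <- if (isTRUE(cfg$generate)) out("fluorescence.csv") else cfg$paths$fluorescence
  traitPath <- if (isTRUE(cfg$generate)) out("traits.csv") else cfg$paths$traits
  spectraPaths <- if (isTRUE(cfg$generate))
    file.path(cfg$out_dir, sprintf("spectra_%s.csv", cfg$species))
  else cfg$paths$spectra

  ## ---- stage: fit_aci --------------------------------------------------
  if ("fit_aci" %in% cfg$stages) {
    tab <- readGasExchangeCsv(gasPath)
    cs <- tableToAciCurves(tab)
    if (!length(cs)) stop("stage fit_aci: zero usable curves")
    .log(cfg, "stage fit_aci: %d curves", length(cs))
    rows <- lapply(cs, function(cv) {
      base <- data.frame(species = speciesOf(cv), treatment = treatmentOf(cv),
                         time = timeOfDayOf(cv), replicate = replicateIdOf(cv))
      if (speciesOf(cv) == "maize") {
        fit <- withCallingHandlers(
          tryCatch(fitC4Curve(cv, ciCutoff = cfg$c4$ci_cutoff,
                              KpFixed = cfg$c4$Kp),
                   error = function(e) NULL),
          warning = function(w) { noteWarn(w); invokeRestart("muffleWarning") })
        if (is.null(fit)) fit <- new("C4Fit", Vpmax = NA_real_,
          Kp = cfg$c4$Kp, RdSlope = NA_real_, Amax = NA_real_,
          phi = NA_real_, theta = NA_real_, offset = NA_real_,
          sse = NA_real_, thetaPinned = FALSE, converged = FALSE)
        cbind(base, model = "c4", Vcmax = NA_real_, Jmax = NA_real_,
              Rd = NA_real_, transition_ci = NA_real_,
              as.data.frame(as.list(fitCoefs(fit))),
              converged = isConverged(fit))
      } else {
        fit <- withCallingHandlers(
          tryCatch(fitFvcbBilinear(cv, constants),
                   error = function(e) NULL),
          warning = function(w) { noteWarn(w); invokeRestart("muffleWarning") })
        if (is.null(fit)) fit <- new("FvCBFit", Vcmax = NA_real_,
          Jmax = NA_real_, Rd = NA_real_, transitionCi = NA_real_,
          sse = NA_real_, nPoints = 0L, converged = FALSE)
        cbind(base, model = "c3",
              as.data.frame(as.list(fitCoefs(fit))),
              Vpmax = NA_real_, Kp = NA_real_, Rd_slope = NA_real_,
              Amax = NA_real_, phi = NA_real_, theta = NA_real_,
              offset = NA_real_, converged = isConverged(fit))
      }
    })
    common <- c("species", "treatment", "time", "replicate", "model",
                "Vcmax", "Jmax", "Rd", "transition_ci", "Vpmax", "Kp",
                "Rd_slope", "Amax", "phi", "theta", "offset", "sse",
                "converged")
    fits <- do.call(rbind, lapply(rows, function(r) r[, common]))
    writeCanonicalCsv(fits, out("aci_fits.csv"))
    manifest <- c(manifest, out("aci_fits.csv"))
    counts$fit_aci <- list(curves = length(cs),
                           failed = sum(!fits$converged))
  }

  ## ---- stage: fit_npq --------------------------------------------------
  if ("fit_npq" %in% cfg$stages) {
    traces <- readFluorCsv(fluorPath)
    if (!length(traces)) stop("stage fit_npq: zero usable traces")
    .log(cfg, "stage fit_npq: %d traces", length(traces))
    rows <- lapply(traces, function(tr) {
      withCallingHandlers(
        tryCatch(summariseNpqTrace(tr), error = function(e) NULL),
        warning = function(w) { noteWarn(w); invokeRestart("muffleWarning") })
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("stage fit_npq: all NPQ fits failed")
    npq <- do.call(rbind, rows)
    parts <- strsplit(npq$leaf_id, "_")
    npq$species <- vapply(parts, `[`, character(1), 1L)
    npq$treatment <- vapply(parts, `[`, character(1), 2L)
    npq <- npq[order(npq$leaf_id, npq$instrument), ]
    rownames(npq) <- NULL
    writeCanonicalCsv(npq, out("npq_fits.csv"))
    manifest <- c(manifest, out("npq_fits.csv"))
    counts$fit_npq <- list(traces = length(traces),
                           failed = sum(!npq$converged))
  }

  ## ---- stage: spectra --------------------------------------------------
  if ("spectra" %in% cfg$stages) {
    testRows <- list()
    idxRows <- list()
    for (f in spectraPaths) {
      ss <- averageTechnicalReps(readSpectraCsv(f))
      sp <- as.character(colData(ss)$species[1L])
      for (tm in unique(colData(ss)$time_of_day)) {
        res <- withCallingHandlers(
          spectraWideAnova(ss, alpha = cfg$alpha, time = tm),
          warning = function(w) { noteWarn(w); invokeRestart("muffleWarning") })
        res$species <- sp
        res$time <- tm
        testRows[[length(testRows) + 1L]] <- res
      }
      idxRows[[length(idxRows) + 1L]] <- computeIndices(ss)
    }
    if (!length(testRows)) stop("stage spectra: zero usable spectra")
    tests <- do.call(rbind, testRows)
    writeCanonicalCsv(tests, out("spectra_tests.csv"))
    indices <- do.call(rbind, idxRows)
    writeCanonicalCsv(indices, out("indices.csv"))
    manifest <- c(manifest, out("spectra_tests.csv"), out("indices.csv"))
    counts$spectra <- list(
      tests = nrow(tests),
      significant = sum(tests$significant),
      index_rows = nrow(indices))
  }

  ## ---- stage: infer ----------------------------------------------------
  if ("infer" %in% cfg$stages) {
    inferRows <- list()
    addRow <- function(species, trait, method, effect, statistic, dfn, dfd, p)
      inferRows[[length(inferRows) + 1L]] <<- data.frame(
        species = species, trait = trait, method = method, effect = effect,
        statistic = statistic, df_num = dfn, df_den = dfd, p = p)
    tryInfer <- function(expr) {
      withCallingHandlers(
        tryCatch(expr, error = function(e) { noteWarn(e); NULL }),
        warning = function(w) { noteWarn(w); invokeRestart("muffleWarning") })
    }
    traits <- read.csv(traitPath)
    for (sp in unique(traits$species)) {
      for (tr in unique(traits$trait[traits$species == sp])) {
        tb <- traits[traits$species == sp & traits$trait == tr, ]
        if (all(is.na(tb$time_of_day)) || tr %in% cfg$no_time_traits) {
          res <- tryInfer(compareTreatmentsT(
            tb$value[tb$treatment == "excised"],
            tb$value[tb$treatment == "attached"]))
          if (!is.null(res))
            addRow(sp, tr, "welch_t", "treatment", res$t, NA, res$df, res$p)
        } else {
          res <- tryInfer(twoWayRmAnova(tb))
          if (!is.null(res))
            for (i in seq_len(nrow(res)))
              addRow(sp, tr, "rm_anova", res$effect[i], res$F[i],
                     res$df_num[i], res$df_den[i], res$p[i])
        }
      }
    }
    ## capacity parameters from the fitted curves (AM/PM repeated measures)
    if (file.exists(out("aci_fits.csv"))) {
      fits <- read.csv(out("aci_fits.csv"))
      fits <- fits[fits$converged == TRUE | fits$converged == "TRUE", ]
      for (sp in unique(fits$species)) {
        sub <- fits[fits$species == sp, ]
        pars <- if (sp == "maize") c("Vpmax", "Amax") else c("Vcmax", "Jmax")
        for (pn in pars) {
          tb <- data.frame(replicate_id = sub$replicate,
                           treatment = sub$treatment,
                           time_of_day = sub$time, value = sub[[pn]])
          res <- tryInfer(twoWayRmAnova(tb))
          if (!is.null(res))
            for (i in seq_len(nrow(res)))
              addRow(sp, pn, "rm_anova", res$effect[i], res$F[i],
                     res$df_num[i], res$df_den[i], res$p[i])
        }
      }
    }
    ## fluorescence scalar traits (t-tests, instruments never pooled)
    if (file.exists(out("npq_fits.csv"))) {
      npq <- read.csv(out("npq_fits.csv"))
      for (instr in unique(npq$instrument)) {
        sub0 <- npq[npq$instrument == instr & npq$converged %in% c(TRUE, "TRUE"), ]
        for (sp in unique(sub0$species)) {
          sub <- sub0[sub0$species == sp, ]
          for (pn in c("fvfm", "b_ind", "b_rel", "max_npq")) {
            res <- tryInfer(compareTreatmentsT(
              sub[[pn]][sub$treatment == "excised"],
              sub[[pn]][sub$treatment == "attached"]))
            if (!is.null(res))
              addRow(sp, paste0(pn, "_", instr), "welch_t", "treatment",
                     res$t, NA, res$df, res$p)
          }
        }
      }
    }
    ## reflectance indices (repeated measures across AM/PM)
    if (file.exists(out("indices.csv"))) {
      idx <- read.csv(out("indices.csv"))
      for (sp in unique(idx$species)) {
        sub <- idx[idx$species == sp, ]
        for (pn in names(indexRegistry())) {
          tb <- data.frame(replicate_id = sub$leaf_id,
                           treatment = sub$treatment,
                           time_of_day = sub$time_of_day,
                           value = sub[[pn]])
          res <- tryInfer(twoWayRmAnova(tb))
          if (!is.null(res))
            for (i in seq_len(nrow(res)))
              addRow(sp, pn, "rm_anova", res$effect[i], res$F[i],
                     res$df_num[i], res$df_den[i], res$p[i])
        }
      }
    }
    if (!length(inferRows)) stop("stage infer: zero usable records")
    inference <- do.call(rbind, inferRows)
    writeCanonicalCsv(inference, out("inference.csv"))
    manifest <- c(manifest, out("inference.csv"))
    counts$infer <- list(tests = nrow(inference))
  }

  report <- list(
    package = "leafPhys",
    version = as.character(packageVersion("leafPhys")),
    seed = cfg$seed,
    stages = cfg$stages,
    species = cfg$species,
    manifest = lapply(manifest, function(f)
      list(file = basename(f), exists = file.exists(f))),
    counts = counts,
    warnings = warnLog,
    config = unclass(cfg)[setdiff(names(cfg), "stages")]
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  .log(cfg, "pipeline complete: %d output files", length(manifest))
  invisible(report)
}
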