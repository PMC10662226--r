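## Independent oracles used to cross-check the fitting and inference code.
## These deliberately share no code with the implementation paths they
## verify.

relErr <- function(est, truth) abs(est - truth) / abs(truth)

## seeded Gaussian noise for hand-built fixtures
.leafPhysNoise <- function(seed, n, sd) {
  set.seed(seed)
  rnorm(n, 0, sd)
}

## Brute-force lattice search over (Vcmax, Jmax, Rd) for the FvCB min-model
## SSE: the oracle the bilinear fit is compared against. The lattice is
## centred on the generating truth.
gridOracleSse <- function(curve, constants = kineticConstants(),
                          truth = list(Vcmax = 100, Jmax = 180, Rd = 1.5),
                          n = 50, span = 0.25, rdRange = c(0, 3)) {
  pts <- aciPoints(curve)
  ci <- pts$ci
  A <- pts$A
  g <- constants@gammastar
  Km <- kmOf(constants)
  x1 <- (ci - g) / (ci + Km)
  x2 <- (ci - g) / (4 * ci + 8 * g)
  V <- seq(truth$Vcmax * (1 - span), truth$Vcmax * (1 + span), length.out = n)
  J <- seq(truth$Jmax * (1 - span), truth$Jmax * (1 + span), length.out = n)
  Rd <- seq(rdRange[1], rdRange[2], length.out = n)
  acMat <- outer(V, x1)                        # n x npts
  ajMat <- outer(J, x2)
  idxV <- rep(seq_len(n), times = n)
  idxJ <- rep(seq_len(n), each = n)
  MM <- pmin(acMat[idxV, , drop = FALSE], ajMat[idxJ, , drop = FALSE])
  D <- MM - matrix(A, nrow = nrow(MM), ncol = length(A), byrow = TRUE)
  S1 <- rowSums(D^2)
  S2 <- rowSums(D)
  npts <- length(A)
  ## SSE(V,J,Rd) = S1 - 2 Rd S2 + npts Rd^2, minimised over the Rd lattice
  best <- Inf
  for (r in Rd) {
    sse <- S1 - 2 * r * S2 + npts * r^2
    m <- min(sse)
    if (m < best) best <- m
  }
  best
}

## Textbook sums-of-squares decomposition for the balanced two-way
## mixed-design ANOVA (between: treatment, within: time), computed from
## cell/subject means only.
rmAnovaOracle <- function(table) {
  wide <- merge(
    table[table$time_of_day == "AM", c("replicate_id", "treatment", "value")],
    table[table$time_of_day == "PM", c("replicate_id", "value")],
    by = "replicate_id", suffixes = c("_AM", "_PM"))
  y <- rbind(
    data.frame(s = wide$replicate_id, g = wide$treatment, t = "AM",
               v = wide$value_AM),
    data.frame(s = wide$replicate_id, g = wide$treatment, t = "PM",
               v = wide$value_PM))
  grand <- mean(y$v)
  N <- nrow(wide)                      # subjects
  k <- length(unique(y$g))
  ng <- tapply(wide$value_AM, wide$treatment, length)
  subjMean <- tapply(y$v, y$s, mean)
  grpMean <- tapply(y$v, y$g, mean)
  timeMean <- tapply(y$v, y$t, mean)
  cellMean <- tapply(y$v, list(y$g, y$t), mean)

  ssTreat <- 2 * sum(ng * (grpMean - grand)^2)
  ssSubj <- 2 * sum((subjMean - grand)^2)
  ssSubjWithin <- ssSubj - ssTreat
  ssTime <- N * sum((timeMean - grand)^2)
  ssInt <- sum(rep(ng, times = 2) *
                 (as.vector(cellMean) - rep(grpMean, times = 2) -
                    rep(timeMean, each = k) + grand)^2)
  gOfS <- setNames(wide$treatment, wide$replicate_id)
  resid <- y$v - subjMean[y$s] - cellMean[cbind(gOfS[y$s], y$t)] +
    grpMean[gOfS[y$s]]
  ssErr <- sum(resid^2)

  Ftreat <- (ssTreat / (k - 1)) / (ssSubjWithin / (N - k))
  Ftime <- (ssTime / 1) / (ssErr / (N - k))
  Fint <- (ssInt / (k - 1)) / (ssErr / (N - k))
  data.frame(
    effect = c("treatment", "time", "interaction"),
    F = c(Ftreat, Ftime, Fint),
    p = c(pf(Ftreat, k - 1, N - k, lower.tail = FALSE),
          pf(Ftime, 1, N - k, lower.tail = FALSE),
          pf(Fint, k - 1, N - k, lower.tail = FALSE)))
}

## balanced repeated-measures table with configurable effects
makeRmTable <- function(n = 8, seed = 1, treatDelta = 0, timeDelta = 0,
                        interDelta = 0, noiseSd = 1, baseline = 0) {
  d <- experimentDesign("tomato", n, seed = seed, effects = list(
    y = effectSpec(baseline = baseline, treatmentDelta = treatDelta,
                   timeDelta = timeDelta, interactionDelta = interDelta,
                   noiseSd = noiseSd)))
  generateTraitTable(d, "y")
}

## minimal SpectraSet built directly from a matrix (for hand-computed cases)
makeSpectraSet <- function(values, wavelength = seq_len(nrow(values)) + 349,
                           treatment = rep(c("attached", "excised"),
                                           each = ncol(values) / 2),
                           time = "AM") {
  meta <- data.frame(
    leaf_id = sprintf("leaf%02d", seq_len(ncol(values))),
    species = "tomato", treatment = treatment, time_of_day = time)
  spectraSet(values, wavelength, meta)
}
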