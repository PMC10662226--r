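test_that("C3 generator emits one point per setpoint and lies on the forward model at zero noise", {
  cv <- generateAciC3(noiseSd = 0, seed = 1)
  pts <- aciPoints(cv)
  expect_equal(nrow(pts), 11L)
  expect_equal(pts$co2_set, co2SequenceC3())
  ## zero A-noise: every AN equals min(Ac, Aj) at the generated ci exactly
  p <- c3TrueParams()
  expected <- pmin(p$Vcmax * (pts$ci - p$gammastar) / (pts$ci + p$Km),
                   p$Jmax * (pts$ci - p$gammastar) / (4 * pts$ci + 8 * p$gammastar)) - p$Rd
  expect_equal(pts$A, expected, tolerance = 1e-12)

  ## determinism: same params + seed -> identical curves
  cv2 <- generateAciC3(noiseSd = 0, seed = 1)
  expect_identical(aciPoints(cv), aciPoints(cv2))
  expect_false(identical(aciPoints(cv),
                         aciPoints(generateAciC3(noiseSd = 0, seed = 2))))

  expect_error(generateAciC3(co2Sequence = c(400, -5)), "positive")
  expect_error(generateAciC3(noiseSd = -1), "noiseSd")
})

test_that("C4 generator concatenates both sequences and approaches the asymptote", {
  cv <- generateAciC4(noiseSd = 0, seed = 3)
  pts <- aciPoints(cv)
  expect_equal(nrow(pts), 12L)
  expect_equal(pts$co2_set, c(co2SequenceC4()$up, co2SequenceC4()$down))

  ## at very large ci the zero-noise response approaches Amax
  far <- generateAciC4(upSequence = c(2e5, 4e5), downSequence = c(100, 50, 25),
                       noiseSd = 0, ciJitterSd = 0, seed = 1)
  expect_equal(max(aciPoints(far)$A), 45, tolerance = 1e-3)

  expect_identical(aciPoints(cv), aciPoints(generateAciC4(noiseSd = 0, seed = 3)))
})

test_that("NPQ trace generator follows the induction/relaxation kinetics exactly at zero noise", {
  tr <- generateNpqTrace(noiseSd = 0, seed = 1)
  p <- pulses(tr)
  expect_equal(sum(p$phase == "induction"), 12L)
  expect_equal(sum(p$phase == "relaxation"), 8L)

  s <- npqSeries(tr)
  ## first induction pulse at t = 0 has NPQ = 0
  expect_equal(s$npq[s$phase == "induction"][1], 0, tolerance = 1e-12)
  ## all induction pulses on a(1 - e^{-bt}), relaxation on a e^{-bt} + c
  ti <- s$t[s$phase == "induction"]
  expect_equal(s$npq[s$phase == "induction"], 2.5 * (1 - exp(-0.4 * ti)),
               tolerance = 1e-12)
  tr2 <- s$t[s$phase == "relaxation"]
  expect_equal(s$npq[s$phase == "relaxation"], 2 * exp(-0.5 * tr2) + 0.4,
               tolerance = 1e-12)

  ## relaxation t -> infinity approaches the offset c
  far <- generateNpqTrace(noiseSd = 0, seed = 1,
                          protocol = list(induction = c(0, 1, 2, 3),
                                          relaxation = c(1, 2, 5, 500)))
  sf <- npqSeries(far)
  expect_equal(tail(sf$npq, 1), 0.4, tolerance = 1e-10)

  ## round trip: Fm' = Fm/(NPQ+1) followed by computeNpq is the identity
  expect_equal(computeNpq(tr@FmDark, tr@FmDark / (s$npq + 1)), s$npq,
               tolerance = 1e-12)

  expect_error(generateNpqTrace(protocol = list(induction = c(0, 2, 1),
                                                relaxation = c(1, 2, 3, 4))),
               "increasing")
  expect_error(generateNpqTrace(aInd = -1), "non-negative")
})

test_that("spectra generator produces the full grid, bounded values and localized treatment effects", {
  d <- experimentDesign("tomato", 3, seed = 7)
  ss <- generateSpectra(d, nTechnical = 3, noiseSd = 0.01)
  expect_s4_class(ss, "SpectraSet")
  expect_equal(wavelengths(ss), 350:2500)
  expect_equal(dim(ss), c(2151L, 3L * 2L * 2L * 3L))
  refl <- SummarizedExperiment::assay(ss, "reflectance")
  expect_true(all(refl >= 0 & refl <= 1))

  ## null case: treatment means differ only through noise (more leaves so
  ## the per-leaf brightness offsets average out)
  dNull <- experimentDesign("tomato", 8, seed = 8)
  avg <- averageTechnicalReps(generateSpectra(dNull, nTechnical = 3,
                                              noiseSd = 0.01))
  cd <- SummarizedExperiment::colData(avg)
  m <- SummarizedExperiment::assay(avg, "reflectance")
  diffNull <- rowMeans(m[, cd$treatment == "excised"]) -
    rowMeans(m[, cd$treatment == "attached"])
  expect_lt(max(abs(diffNull)), 0.02)

  ## a single negative band on excised leaves lowers them exactly there
  band <- data.frame(center = 1940, width = 50, amplitude = -0.05)
  ss2 <- generateSpectra(d, effectBands = band, nTechnical = 1, noiseSd = 0,
                         leafSd = 0)
  cd2 <- SummarizedExperiment::colData(ss2)
  m2 <- SummarizedExperiment::assay(ss2, "reflectance")
  diff2 <- rowMeans(m2[, cd2$treatment == "excised"]) -
    rowMeans(m2[, cd2$treatment == "attached"])
  wl <- wavelengths(ss2)
  inBand <- abs(wl - 1940) <= 50
  farOut <- abs(wl - 1940) > 300
  expect_true(all(diff2[inBand] < 0))
  expect_lt(max(abs(diff2[farOut])), 1e-6)

  expect_error(generateSpectra(d, effectBands = data.frame(
    center = 3000, width = 50, amplitude = 0.1)), "grid")
})

test_that("trait tables realise the additive effect structure exactly at zero noise", {
  d0 <- experimentDesign("maize", 4, seed = 1, effects = list(
    x = effectSpec(baseline = 2, noiseSd = 0)))
  t0 <- generateTraitTable(d0, "x")
  expect_true(all(t0$value == 2))
  expect_equal(nrow(t0), 4L * 2L * 2L)

  d1 <- experimentDesign("maize", 4, seed = 1, effects = list(
    x = effectSpec(baseline = 1, treatmentDelta = -0.05, noiseSd = 0)))
  t1 <- generateTraitTable(d1, "x")
  expect_equal(mean(t1$value[t1$treatment == "excised"]) -
                 mean(t1$value[t1$treatment == "attached"]), -0.05)

  ## repeated measures: the same replicate id appears at both times
  expect_true(all(table(t1$replicate_id) == 2L))

  ## adding replicates never perturbs existing rows
  dBig <- experimentDesign("maize", 6, seed = 1, effects = d1@effects)
  tBig <- generateTraitTable(dBig, "x")
  shared <- merge(t1, tBig, by = c("replicate_id", "time_of_day"))
  expect_equal(shared$value.x, shared$value.y)

  expect_error(generateTraitTable(d1, "nope"), "unknown trait")
})

test_that("a barley water-potential-like shift is detected by the t-test in most seeds", {
  ## attached baseline -0.237 MPa, excision shift +0.044 MPa, sd 0.02, n = 8
  hits <- vapply(1:200, function(s) {
    d <- experimentDesign("barley", 8, seed = s, effects = list(
      wp = effectSpec(baseline = -0.237, treatmentDelta = 0.044,
                      noiseSd = 0.02)))
    tb <- generateTraitTable(d, "wp", withTime = FALSE)
    res <- compareTreatmentsT(tb$value[tb$treatment == "excised"],
                              tb$value[tb$treatment == "attached"])
    res$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("experiment design enforces its invariants", {
  expect_error(experimentDesign("barley", 1), "nRepsPerTreatment")
  expect_error(effectSpec(noiseSd = -1), "noiseSd")
  expect_equal(defaultReps("tomato"), 10L)
  expect_equal(defaultReps("barley"), 8L)
  expect_equal(defaultReps("maize"), 12L)
})
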