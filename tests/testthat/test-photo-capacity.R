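test_that("bilinear FvCB fit recovers noiseless curves exactly", {
  for (s in 1:5) {
    cv <- generateAciC3(noiseSd = 0, seed = s)
    f <- fitFvcbBilinear(cv)
    expect_true(isConverged(f))
    co <- fitCoefs(f)
    expect_lt(relErr(co[["Vcmax"]], 100), 1e-8)
    expect_lt(relErr(co[["Jmax"]], 180), 1e-8)
    expect_lt(abs(co[["Rd"]] - 1.5), 1e-8)
    pts <- aciPoints(cv)
    expect_gte(co[["transition_ci"]], min(pts$ci))
    expect_lte(co[["transition_ci"]], max(pts$ci))
  }
})

test_that("bilinear fit SSE never exceeds the lattice oracle SSE", {
  for (s in 1:6) {
    noise <- if (s %% 2 == 0) 0.1 else 0
    cv <- generateAciC3(noiseSd = noise, seed = s)
    f <- fitFvcbBilinear(cv)
    expect_lte(fitCoefs(f)[["sse"]], gridOracleSse(cv) + 1e-6)
  }
})

test_that("bilinear fit degrades gracefully with noise and is unbiased as noise shrinks", {
  errsAt <- function(sd, seeds) {
    t(vapply(seeds, function(s) {
      co <- fitCoefs(fitFvcbBilinear(generateAciC3(noiseSd = sd, seed = s)))
      c((co[["Vcmax"]] - 100) / 100, (co[["Jmax"]] - 180) / 180)
    }, numeric(2)))
  }
  e03 <- errsAt(0.3, 1:60)
  expect_lte(median(abs(e03[, 1])), 0.10)
  expect_lte(median(abs(e03[, 2])), 0.10)
  ## bias shrinks with the noise level
  e06 <- errsAt(0.6, 1:60)
  e005 <- errsAt(0.05, 1:60)
  expect_lt(abs(mean(e005[, 1])), 0.005)
  expect_lt(abs(mean(e03[, 1])), 0.03)
  expect_lt(abs(mean(e06[, 1])), 0.06)
})

test_that("bilinear fit rejects short and flags degenerate inputs", {
  cv <- generateAciC3(noiseSd = 0, seed = 1)
  short <- aciCurve(aciPoints(cv)[1:5, ])
  expect_error(fitFvcbBilinear(short), "6 points")
  ## collinear-flat curve cannot yield positive capacities
  flat <- aciCurve(data.frame(co2_set = co2SequenceC3(),
                              ci = 0.7 * co2SequenceC3(),
                              A = rep(5, 11) - seq(0, 1, length.out = 11),
                              gs = 0.3))
  expect_warning(ff <- fitFvcbBilinear(flat), "failed")
  expect_false(isConverged(ff))
})

test_that("Vpmax initial-slope fit is exact on noiseless PEPc-limited points", {
  ci <- c(10, 25, 50, 80)
  cv <- aciCurve(data.frame(co2_set = ci / 0.4, ci = ci,
                            A = c4PepcLimited(ci, 110, 80, 2), gs = 0.2),
                 species = "maize")
  fit <- fitVpmax(cv, ciCutoff = 100, KpFixed = 80)
  expect_true(fit$converged)
  expect_lt(relErr(fit$Vpmax, 110), 1e-3)
  expect_lt(abs(fit$RdSlope - 2), 1e-6)
  expect_lt(fit$sse, 1e-16)

  ## degenerate: identical A values -> zero slope -> failed-fit signal
  flat <- aciCurve(data.frame(co2_set = ci, ci = ci, A = rep(3, 4), gs = 0.2))
  expect_warning(fd <- fitVpmax(flat), "degenerate")
  expect_false(fd$converged)

  expect_error(fitVpmax(cv, ciCutoff = 20), "need >= 3")
})

test_that("Vpmax recovery stays within 10% (median) under measurement noise", {
  ci <- 0.4 * co2SequenceC4()$down  # 160 120 100 80 40 30 10
  errs <- vapply(1:60, function(s) {
    A <- c4PepcLimited(ci, 110, 80, 2) +
      .leafPhysNoise(s, length(ci), 0.5)
    cv <- aciCurve(data.frame(co2_set = ci, ci = ci, A = A, gs = 0.2))
    relErr(fitVpmax(cv)$Vpmax, 110)
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("hyperbola fit recovers the asymptote and respects its intercept", {
  ## generating curve: phi 0.55, Asat 47, theta 0.7, offset -2 -> Amax 45
  cv <- generateAciC4(noiseSd = 0, ciJitterSd = 0, seed = 1)
  f <- fitNrhAmax(cv)
  expect_true(isConverged(f))
  co <- fitCoefs(f)
  expect_lt(relErr(co[["Amax"]], 45), 0.005)
  expect_lt(relErr(co[["phi"]], 0.55), 0.01)
  expect_lt(relErr(co[["theta"]], 0.7), 0.01)
  ## fitted function value at ci = 0 equals the offset
  expect_equal(nonRectHyperbola(0, co[["phi"]], co[["Amax"]] - co[["offset"]],
                                co[["theta"]], co[["offset"]]),
               co[["offset"]])

  ## combined C4 fit carries both parameter groups
  full <- fitC4Curve(cv)
  expect_true(isConverged(full))
  expect_lt(relErr(fitCoefs(full)[["Amax"]], 45), 0.005)
})

test_that("Amax recovery stays within 10% (median) under measurement noise", {
  errs <- vapply(1:40, function(s) {
    cv <- generateAciC4(noiseSd = 0.5, seed = s)
    relErr(fitCoefs(fitNrhAmax(cv))[["Amax"]], 45)
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})
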