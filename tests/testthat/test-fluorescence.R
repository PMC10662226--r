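test_that("kinetic model values match direct arithmetic", {
  ## induction a(1 - e^{-bt}) at a=2.5, b=0.4, t=2.5
  expect_equal(2.5 * (1 - exp(-0.4 * 2.5)), 1.5803, tolerance = 1e-4)
  tr <- generateNpqTrace(noiseSd = 0, seed = 1,
                         protocol = list(induction = c(0, 1, 2.5, 5, 8),
                                         relaxation = c(1, 2, 4, 8)))
  s <- npqSeries(tr)
  expect_equal(s$npq[s$phase == "induction"][3], 2.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  ## relaxation a e^{-bt} + c at a=2, b=0.5, c=0.4, t=2
  expect_equal(s$npq[s$phase == "relaxation"][2], 2 * exp(-1) + 0.4,
               tolerance = 1e-12)
  expect_equal(2 * exp(-1) + 0.4, 1.1358, tolerance = 1e-4)
})

test_that("induction and relaxation fits recover noiseless parameters", {
  tr <- generateNpqTrace(noiseSd = 0, seed = 1)
  ind <- fitInduction(tr)
  expect_true(isConverged(ind))
  expect_lt(relErr(fitCoefs(ind)[["a"]], 2.5), 0.005)
  expect_lt(relErr(fitCoefs(ind)[["b"]], 0.4), 0.005)
  expect_true(is.na(fitCoefs(ind)[["c"]]))
  ## noiseless fit of a trace whose first point is (0, 0): zero residual there
  expect_lt(fitCoefs(ind)[["rmse"]], 1e-8)

  rel <- fitRelaxation(tr)
  expect_true(isConverged(rel))
  expect_lt(relErr(fitCoefs(rel)[["a"]], 2.0), 0.005)
  expect_lt(relErr(fitCoefs(rel)[["b"]], 0.5), 0.005)
  expect_lt(relErr(fitCoefs(rel)[["c"]], 0.4), 0.005)
})

test_that("parameter recovery holds under multiplicative noise (median over seeds)", {
  res <- t(vapply(1:40, function(s) {
    tr <- generateNpqTrace(noiseSd = 0.02, seed = s)
    ind <- fitCoefs(fitInduction(tr))
    rel <- fitCoefs(fitRelaxation(tr))
    c(relErr(ind[["a"]], 2.5), relErr(ind[["b"]], 0.4),
      relErr(rel[["a"]], 2.0), relErr(rel[["b"]], 0.5))
  }, numeric(4)))
  med <- apply(res, 2, median)
  expect_lte(med[1], 0.05)   # induction amplitude
  expect_lte(med[2], 0.10)   # induction rate
  expect_lte(med[3], 0.05)   # relaxation amplitude
  expect_lte(med[4], 0.10)   # relaxation rate
})

test_that("maximum NPQ is the observed induction maximum", {
  tr <- generateNpqTrace(noiseSd = 0, seed = 1)
  s <- npqSeries(tr)
  ## monotone saturating trace: max equals the last induction pulse
  expect_equal(maxNpq(tr), max(s$npq[s$phase == "induction"]))
  expect_equal(maxNpq(tr), 2.5 * (1 - exp(-0.4 * 10)), tolerance = 1e-12)
  expect_equal(maxNpq(tr), 2.454, tolerance = 1e-3)

  ## a transient overshoot defines the maximum
  over <- fluorTrace(data.frame(
    phase = "induction", t = c(0, 1, 2, 3, 4),
    Fm_prime = 2 / (c(0, 1.2, 2.9, 2.3, 2.4) + 1)), FmDark = 2, Fo = 0.4)
  expect_equal(maxNpq(over), 2.9, tolerance = 1e-12)
})

test_that("fits depend on fluorescence only through NPQ", {
  tr <- generateNpqTrace(noiseSd = 0.02, seed = 11)
  p <- pulses(tr)
  ## rescaling Fm and all Fm' jointly leaves NPQ, hence the fits, unchanged
  scaled <- fluorTrace(transform(p, Fm_prime = Fm_prime * 3.7),
                       FmDark = tr@FmDark * 3.7, Fo = tr@Fo * 3.7,
                       leafId = tr@leafId)
  expect_equal(fitCoefs(fitRelaxation(tr)), fitCoefs(fitRelaxation(scaled)),
               tolerance = 1e-6)
  expect_equal(fitCoefs(fitInduction(tr)), fitCoefs(fitInduction(scaled)),
               tolerance = 1e-6)
})

test_that("fits guard their preconditions", {
  few <- fluorTrace(data.frame(phase = "induction", t = c(0, 1, 2),
                               Fm_prime = c(2, 1.5, 1.2)),
                    FmDark = 2, Fo = 0.4)
  expect_error(fitInduction(few), "4 pulses")
  neg <- fluorTrace(data.frame(phase = "induction", t = 0:4,
                               Fm_prime = rep(2.5, 5)),
                    FmDark = 2, Fo = 0.4)
  expect_error(fitInduction(neg), "non-positive")
  expect_error(fluorTrace(data.frame(phase = "induction", t = c(0, 0, 1, 2),
                                     Fm_prime = c(2, 2, 2, 2)),
                          FmDark = 2, Fo = 0.4), "increasing")
})

test_that("trace summary collects the per-leaf scalars", {
  tr <- generateNpqTrace(noiseSd = 0, seed = 2, fvfm = 0.8)
  s <- summariseNpqTrace(tr)
  expect_equal(s$fvfm, 0.8)
  expect_true(s$converged)
  expect_equal(s$a_ind, 2.5, tolerance = 1e-3)
  expect_equal(s$c_rel, 0.4, tolerance = 1e-3)
})
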