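test_that("technical-replicate averaging is the element-wise mean", {
  wl <- 350:360
  one <- baseLeafSpectrum(wl)
  vals <- cbind(one, one + 0.2, one + 0.4)
  meta <- data.frame(leaf_id = "leafA", species = "tomato",
                     treatment = "attached", time_of_day = "AM",
                     technical_rep = 1:3)
  ss <- spectraSet(pmin(vals, 1), wl, meta)
  avg <- averageTechnicalReps(ss)
  expect_equal(ncol(avg), 1L)
  expect_equal(unname(SummarizedExperiment::assay(avg, "reflectance")[, 1]),
               unname(pmin(vals, 1) %*% rep(1 / 3, 3))[, 1])

  ## three identical spectra average to themselves; single is unchanged
  same <- spectraSet(cbind(one, one, one), wl, meta)
  expect_equal(unname(SummarizedExperiment::assay(
    averageTechnicalReps(same), "reflectance")[, 1]), unname(one))
  single <- spectraSet(matrix(one), wl, meta[1, ])
  expect_equal(unname(SummarizedExperiment::assay(
    averageTechnicalReps(single), "reflectance")[, 1]), unname(one))
})

test_that("index registry evaluates formulas with nearest-band lookup and guards", {
  wl <- defaultWavelengthGrid()
  flat <- rep(0.5, length(wl))
  expect_equal(computeIndex(flat, wl, "MSI"), 1)
  expect_equal(computeIndex(flat, wl, "WI"), 1)
  expect_equal(computeIndex(flat, wl, "NDVI"), 0)
  expect_equal(computeIndex(flat, wl, "PRI"), 0)
  ## flat spectrum: Datt denominator is zero -> NA with a warning
  expect_warning(v <- computeIndex(flat, wl, "Datt"), "undefined")
  expect_true(is.na(v))

  ## hand-built spectrum: R850=0.5, R710=0.3, R680=0.1 -> Datt 0.5
  sp <- flat
  sp[wl == 850] <- 0.5; sp[wl == 710] <- 0.3; sp[wl == 680] <- 0.1
  expect_equal(computeIndex(sp, wl, "Datt"), (0.5 - 0.3) / (0.5 - 0.1))

  ## bands outside the grid are rejected
  expect_error(computeIndex(flat, 400:500, "Datt"), "outside")
  expect_error(computeIndex(flat, wl, "nope"), "unknown index")
})

test_that("Bonferroni threshold divides alpha by the tests actually run", {
  expect_equal(bonferroniThreshold(0.05, 2151), 0.05 / 2151)
  expect_equal(bonferroniThreshold(0.05, 2151), 2.3245e-5, tolerance = 1e-4)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), "positive")
  expect_error(bonferroniThreshold(1.2, 10))
})

test_that("per-wavelength ANOVA matches hand-computed F and the t-test equivalence", {
  ## groups [1,2,3] vs [2,3,4] (scaled into [0,1]): SSB = 1.5, SSW = 4
  vals <- matrix(c(1, 2, 3, 2, 3, 4) / 10, nrow = 1)
  ss <- makeSpectraSet(rbind(vals, vals), wavelength = c(400, 401))
  res <- spectraWideAnova(ss)
  expect_equal(res$F[1], 1.5, tolerance = 1e-12)
  expect_equal(res$df_num[1], 1L)
  expect_equal(res$df_den[1], 4L)

  ## two-group F equals the squared pooled t, with identical p
  set.seed(99)
  m <- matrix(runif(5 * 8, 0.2, 0.6), nrow = 5)
  ss2 <- makeSpectraSet(m, wavelength = 400:404)
  res2 <- spectraWideAnova(ss2)
  for (i in 1:5) {
    tt <- t.test(m[i, 1:4], m[i, 5:8], var.equal = TRUE)
    expect_equal(res2$F[i], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res2$p[i], tt$p.value, tolerance = 1e-10)
  }
  ## -log10 p reported and monotone in p
  expect_equal(res2$neglog10_p, -log10(res2$p))
  ord <- order(res2$p)
  expect_true(all(diff(res2$neglog10_p[ord]) <= 1e-12))
})

test_that("degenerate wavelengths and small groups are handled explicitly", {
  const <- matrix(0.4, nrow = 2, ncol = 6)
  const[2, ] <- c(0.1, 0.2, 0.3, 0.2, 0.3, 0.4)
  ss <- makeSpectraSet(const, wavelength = c(500, 501))
  expect_warning(res <- spectraWideAnova(ss), "zero variance")
  expect_equal(res$F[1], 0)
  expect_equal(res$p[1], 1)

  tiny <- makeSpectraSet(matrix(c(0.1, 0.2, 0.3), nrow = 1),
                         wavelength = 500,
                         treatment = c("attached", "attached", "excised"))
  expect_error(spectraWideAnova(tiny), "at least 2")
})

test_that("an injected effect band produces the minimum p inside that band", {
  d <- experimentDesign("barley", 8, seed = 21)
  band <- data.frame(center = 1450, width = 40, amplitude = -0.04)
  ss <- generateSpectra(d, effectBands = band, nTechnical = 3,
                        noiseSd = 0.01)
  res <- spectraWideAnova(averageTechnicalReps(ss), time = "AM")
  wlMin <- res$wavelength[which.min(res$p)]
  expect_lt(abs(wlMin - 1450), 40)
  ## and the spectra-wide minimum is Bonferroni-significant for this amplitude
  expect_true(any(res$significant))
})

test_that("unaveraged technical replicates are rejected", {
  d <- experimentDesign("tomato", 3, seed = 1)
  ss <- generateSpectra(d, nTechnical = 2, noiseSd = 0.01)
  expect_error(spectraWideAnova(ss), "average technical replicates")
})
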