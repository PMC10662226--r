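test_that("mixed-design ANOVA equals the textbook decomposition and aov on balanced data", {
  for (s in 1:4) {
    tb <- makeRmTable(n = 6, seed = s, treatDelta = 0.4, timeDelta = -0.3,
                      interDelta = 0.2, noiseSd = 1)
    mine <- twoWayRmAnova(tb)
    oracle <- rmAnovaOracle(tb)
    expect_equal(mine$F, oracle$F, tolerance = 1e-8)
    expect_equal(mine$p, oracle$p, tolerance = 1e-8)

    ## independent route: stats::aov with an Error(subject) stratum
    tb$treatment <- factor(tb$treatment)
    tb$time_of_day <- factor(tb$time_of_day)
    a <- summary(aov(value ~ treatment * time_of_day + Error(replicate_id),
                     data = tb))
    fTreat <- a[["Error: replicate_id"]][[1]]["treatment", "F value"]
    within <- a[["Error: Within"]][[1]]
    expect_equal(mine$F[mine$effect == "treatment"], fTreat,
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "time"],
                 within["time_of_day", "F value"], tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "interaction"],
                 within["treatment:time_of_day", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("unbalanced designs use marginal tests and drop incomplete replicates", {
  tb <- makeRmTable(n = 8, seed = 3, treatDelta = 0.5, noiseSd = 1)
  ## unbalance: drop two excised subjects entirely
  drop <- unique(tb$replicate_id[tb$treatment == "excised"])[1:2]
  tb2 <- tb[!tb$replicate_id %in% drop, ]
  res <- twoWayRmAnova(tb2)
  ## treatment F equals the one-way ANOVA on subject means
  wide <- merge(tb2[tb2$time_of_day == "AM", c("replicate_id", "treatment", "value")],
                tb2[tb2$time_of_day == "PM", c("replicate_id", "value")],
                by = "replicate_id")
  m <- (wide$value.x + wide$value.y) / 2
  ow <- anova(lm(m ~ factor(wide$treatment)))
  expect_equal(res$F[res$effect == "treatment"], ow$`F value`[1],
               tolerance = 1e-10)

  ## replicates with a missing time point are dropped with a warning
  tb3 <- tb[!(tb$replicate_id == tb$replicate_id[1] & tb$time_of_day == "PM"), ]
  expect_warning(res3 <- twoWayRmAnova(tb3), "dropped")
  expect_equal(res3$df_den[1], 13)  # 15 complete subjects - 2 groups
})

test_that("ANOVA p-values are invariant to affine trait rescaling", {
  tb <- makeRmTable(n = 6, seed = 11, treatDelta = 0.3, timeDelta = 0.2,
                    noiseSd = 1)
  res1 <- twoWayRmAnova(tb)
  tb$value <- tb$value * 7.3 - 2.1
  res2 <- twoWayRmAnova(tb)
  expect_equal(res1$F, res2$F, tolerance = 1e-10)
  expect_equal(res1$p, res2$p, tolerance = 1e-10)
})

test_that("degenerate constant responses raise an explicit signal", {
  tb <- makeRmTable(n = 4, seed = 1, noiseSd = 0)
  expect_error(twoWayRmAnova(tb), class = "leafPhys_degenerate")
  expect_error(twoWayRmAnova(tb), "undefined F")
  ## duplicated (replicate, time) rows are rejected
  tb2 <- makeRmTable(n = 4, seed = 1, noiseSd = 1)
  expect_error(twoWayRmAnova(rbind(tb2, tb2[1, ])), "at most once")
})

test_that("treatment t-tests match hand-computed statistics", {
  ## paired differences (2,3,4)-(1,1,1) = (1,2,3): mean 2, sd 1, t = 2*sqrt(3)
  res <- compareTreatmentsT(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$flavor, "one_sample_on_differences")

  ## paired differences (-1, 0, 1): t = 0, p = 1
  res0 <- compareTreatmentsT(c(0, 2, 4), c(1, 2, 3), paired = TRUE)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  ## identical groups: mean difference 0, p = 1
  resId <- compareTreatmentsT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(resId$mean_difference, 0)
  expect_equal(resId$p, 1)
  expect_equal(resId$flavor, "welch_two_sample")

  expect_error(compareTreatmentsT(c(1, 1, 1), c(2, 2, 2)),
               class = "leafPhys_degenerate")
  expect_error(compareTreatmentsT(c(1, 2, 3), c(1, 2), paired = TRUE),
               "equal-length")
})

test_that("Welch t converges to the pooled t for equal variances and sizes", {
  set.seed(50)
  a <- rnorm(50); b <- rnorm(50, 0.3)
  welch <- compareTreatmentsT(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(welch$t, unname(pooled$statistic), tolerance = 1e-6)
  expect_equal(welch$p, pooled$p.value, tolerance = 1e-4)
})

test_that("sampling-date check flags shifts and recommends combining nulls", {
  ## identical values across dates: p = 1, combine
  tbId <- data.frame(trait = "x", date = rep(c("d1", "d2"), each = 4),
                     value = rep(5, 8))
  resId <- samplingDateCheck(tbId)
  expect_equal(resId$p, 1)
  expect_true(resId$combine)

  ## a d = 3 shift at n = 8 per date is flagged with high power
  hits <- vapply(1:60, function(s) {
    v <- c(.leafPhysNoise(s, 8, 1), .leafPhysNoise(s + 1000, 8, 1) + 3)
    tb <- data.frame(trait = "x", date = rep(c("d1", "d2"), each = 8),
                     value = v)
    !samplingDateCheck(tb)$combine
  }, logical(1))
  expect_gt(mean(hits), 0.95)

  ## null type-I: about alpha of traits flagged
  flags <- vapply(1:300, function(s) {
    tb <- data.frame(trait = "x", date = rep(c("d1", "d2"), each = 8),
                     value = .leafPhysNoise(s + 5000, 16, 1))
    !samplingDateCheck(tb)$combine
  }, logical(1))
  expect_lt(abs(mean(flags) - 0.05), 0.035)

  expect_error(samplingDateCheck(data.frame(trait = "x", date = "d1",
                                            value = 1:4)), "exactly 2")
})
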