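## Inference layer: mixed-design (repeated-measures) two-way ANOVA,
## treatment t-tests, sampling-date homogeneity check.

.degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("leafPhys_degenerate", "error")))
}

#' Two-way repeated-measures (mixed design) ANOVA
#'
#' Tests a between-subject treatment factor (attached vs excised), a
#' two-level within-subject time factor (AM vs PM) and their interaction.
#' The treatment effect is tested against the subjects-within-treatment
#' error stratum; time and the interaction against the time x
#' subjects-within-treatment stratum. With a two-level within factor the
#' within-stratum tests are computed exactly on the per-subject PM - AM
#' differences: the time effect is the test of the (unweighted) grand mean
#' of the group means of the differences, and the interaction is the test
#' of the treatment effect on the differences. On balanced data this
#' reproduces the textbook sums-of-squares decomposition; with unbalanced
#' group sizes it gives the marginal (Type-III-style) tests.
#'
#' Replicates missing one of the two time points are dropped listwise with
#' a warning. A constant response (zero residual variance in a stratum)
#' raises a classed error (\code{leafPhys_degenerate}) rather than
#' returning an undefined F.
#'
#' @param table data.frame with columns \code{replicate_id},
#'   \code{treatment}, \code{time_of_day}, \code{value}; each
#'   (replicate, time) combination at most once, replicates nested within
#'   treatment.
#' @return data.frame with one row per effect (\code{treatment},
#'   \code{time}, \code{interaction}) and columns \code{df_num},
#'   \code{df_den}, \code{F}, \code{p}.
#' @examples
#' d <- experimentDesign("maize", seed = 1,
#'        effects = list(gs = effectSpec(0.2, -0.05, noiseSd = 0.025)))
#' twoWayRmAnova(generateTraitTable(d, "gs"))
#' @export
twoWayRmAnova <- function(table) {
  need <- c("replicate_id", "treatment", "time_of_day", "value")
  stopifnot(all(need %in% names(table)))
  if (anyDuplicated(table[, c("replicate_id", "time_of_day")]))
    stop("each (replicate, time) combination may appear at most once")
  wide <- merge(
    table[table$time_of_day == "AM",
          c("replicate_id", "treatment", "value")],
    table[table$time_of_day == "PM", c("replicate_id", "value")],
    by = "replicate_id", suffixes = c("_AM", "_PM"))
  nAll <- length(unique(table$replicate_id))
  if (nrow(wide) < nAll)
    warning(sprintf("%d replicate(s) missing a time point dropped",
                    nAll - nrow(wide)))
  if (nrow(wide) == 0L) stop("no replicate has both time points")
  g <- factor(wide$treatment)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("need at least 2 replicates per treatment after dropping")
  m <- (wide$value_AM + wide$value_PM) / 2   # subject means
  d <- wide$value_PM - wide$value_AM         # within-subject differences
  N <- length(m)
  kg <- nlevels(g)

  ## between-subject stratum: one-way ANOVA on subject means
  gm <- tapply(m, g, mean)
  ssb <- sum(table(g) * (gm - mean(m))^2)
  ssw <- sum((m - gm[g])^2)
  if (ssw < .Machine$double.eps * N)
    .degenerate("undefined F: zero between-subject residual variance")
  Ftreat <- (ssb / (kg - 1)) / (ssw / (N - kg))
  pTreat <- pf(Ftreat, kg - 1, N - kg, lower.tail = FALSE)

  ## within-subject stratum on d, marginal (unweighted-means) tests
  dm <- tapply(d, g, mean)
  ssrd <- sum((d - dm[g])^2)
  if (ssrd < .Machine$double.eps * N)
    .degenerate("undefined F: zero within-subject residual variance")
  msr <- ssrd / (N - kg)
  ## time: unweighted grand mean of group means of d
  wsum <- sum(1 / table(g))
  Ftime <- (mean(dm)^2 * kg^2 / wsum) / msr
  pTime <- pf(Ftime, 1, N - kg, lower.tail = FALSE)
  ## interaction: treatment effect on d
  ssbd <- sum(table(g) * (dm - mean(d))^2)
  Fint <- (ssbd / (kg - 1)) / msr
  pInt <- pf(Fint, kg - 1, N - kg, lower.tail = FALSE)

  data.frame(
    effect = c("treatment", "time", "interaction"),
    df_num = c(kg - 1L, 1L, kg - 1L),
    df_den = c(N - kg, N - kg, N - kg),
    F = c(Ftreat, Ftime, Fint),
    p = c(pTreat, pTime, pInt)
  )
}

#' Compare excised vs attached values with a t-test
#'
#' Default is a Welch two-sample t-test (replicate plants are independent);
#' \code{paired = TRUE} runs a one-sample t-test on the per-pair
#' differences against zero (values must then be aligned by replicate).
#'
#' @param excised,attached Numeric vectors (each length >= 2; equal length
#'   if paired).
#' @param paired Logical.
#' @return data.frame with columns \code{t}, \code{df}, \code{p},
#'   \code{mean_difference} (excised - attached) and \code{flavor}.
#' @examples
#' compareTreatmentsT(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
#' @export
compareTreatmentsT <- function(excised, attached, paired = FALSE) {
  stopifnot(length(excised) >= 2L, length(attached) >= 2L)
  if (paired) {
    if (length(excised) != length(attached))
      stop("paired comparison requires equal-length, aligned vectors")
    d <- excised - attached
    if (sd(d) < .Machine$double.eps)
      .degenerate("undefined t: zero variance of the paired differences")
    tt <- t.test(d, mu = 0)
    flavor <- "one_sample_on_differences"
  } else {
    if (sd(excised) < .Machine$double.eps &&
        sd(attached) < .Machine$double.eps)
      .degenerate("undefined t: zero variance in both groups")
    tt <- t.test(excised, attached, var.equal = FALSE)
    flavor <- "welch_two_sample"
  }
  data.frame(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value,
    mean_difference = mean(excised) - mean(attached),
    flavor = flavor
  )
}

#' Sampling-date homogeneity check
#'
#' Measurements taken over two sampling dates may only be pooled when the
#' date has no detectable effect. For each trait, an unpaired Welch t-test
#' compares the two date groups; traits with p >= alpha are recommended for
#' combining.
#'
#' @param table data.frame with columns \code{trait}, \code{date},
#'   \code{value}; exactly two distinct dates.
#' @param alpha Significance level for the combine recommendation.
#' @return data.frame with one row per trait: \code{trait}, \code{t},
#'   \code{df}, \code{p}, \code{mean_difference}, \code{combine}.
#' @export
samplingDateCheck <- function(table, alpha = 0.05) {
  stopifnot(all(c("trait", "date", "value") %in% names(table)))
  dates <- sort(unique(table$date))
  if (length(dates) != 2L)
    stop("sampling-date check requires exactly 2 date groups")
  out <- lapply(split(table, table$trait), function(tb) {
    g1 <- tb$value[tb$date == dates[1L]]
    g2 <- tb$value[tb$date == dates[2L]]
    ## identical values across dates carry no evidence of a date effect:
    ## map the degenerate zero-variance case to t = 0, p = 1, combine
    res <- tryCatch(compareTreatmentsT(g2, g1, paired = FALSE),
                    leafPhys_degenerate = function(e)
                      data.frame(t = 0, df = NA_real_, p = 1,
                                 mean_difference = mean(g2) - mean(g1),
                                 flavor = "welch_two_sample"))
    data.frame(trait = tb$trait[1L], t = res$t, df = res$df, p = res$p,
               mean_difference = res$mean_difference,
               combine = res$p >= alpha)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
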