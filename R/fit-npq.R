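## NPQ induction/relaxation kinetics.

.npqOfPhase <- function(trace, phase) {
  p <- pulses(trace)
  p <- p[p$phase == phase, , drop = FALSE]
  data.frame(t = p$t, npq = computeNpq(trace@FmDark, p$Fm_prime))
}

#' Per-pulse NPQ values of a trace
#'
#' @param trace A \linkS4class{FluorTrace}.
#' @return data.frame with columns \code{phase}, \code{t}, \code{npq}.
#' @export
npqSeries <- function(trace) {
  p <- pulses(trace)
  data.frame(phase = p$phase, t = p$t,
             npq = computeNpq(trace@FmDark, p$Fm_prime))
}

.npqJitters <- rbind(c(1, 1), c(0.5, 1.6), c(1.8, 0.6))

.fitNpqPhase <- function(tt, npq, phase) {
  if (length(tt) < 4L)
    stop(sprintf("%s fit requires at least 4 pulses", phase))
  if (all(npq <= 0))
    stop(sprintf("%s fit failed: all NPQ values are non-positive", phase))
  df <- data.frame(t = tt, npq = npq)
  if (phase == "induction") {
    a0 <- max(npq[length(npq)], 0.1)
    ## log-linearised rate from the first half: 1 - NPQ/a ~ e^{-bt}
    half <- seq_len(max(2L, floor(length(tt) / 2)))
    frac <- 1 - npq[half] / (a0 * 1.05)
    ok <- frac > 1e-6 & tt[half] > 0
    b0 <- if (sum(ok) >= 2L) {
      bb <- -stats::coef(stats::lm(log(frac[ok]) ~ 0 + tt[half][ok]))[[1L]]
      if (is.finite(bb) && bb > 0) bb else 0.5
    } else 0.5
    form <- npq ~ a * (1 - exp(-b * t))
    start0 <- c(a = a0, b = b0)
    lower <- c(a = 0, b = 0)
    upper <- c(a = Inf, b = Inf)
  } else {
    c0 <- npq[length(npq)]
    a0 <- max(npq[1L] - c0, 0.1)
    pos <- npq - c0 * 0.95
    ok <- pos > 1e-6
    b0 <- if (sum(ok) >= 2L) {
      bb <- -stats::coef(stats::lm(log(pos[ok]) ~ tt[ok]))[[2L]]
      if (is.finite(bb) && bb > 0) bb else 0.5
    } else 0.5
    form <- npq ~ a * exp(-b * t) + c
    start0 <- c(a = a0, b = b0, c = c0)
    lower <- c(a = 0, b = 0, c = -Inf)
    upper <- c(a = Inf, b = Inf, c = Inf)
  }
  best <- NULL
  for (j in seq_len(nrow(.npqJitters))) {
    st <- start0
    st[c("a", "b")] <- st[c("a", "b")] * .npqJitters[j, ]
    st <- pmax(st, lower + 1e-8)
    fit <- tryCatch(
      nlsLM(form, data = df, start = as.list(st), lower = lower,
            upper = upper,
            control = nls.lm.control(maxiter = 200, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- c(as.list(coef(fit)), list(sse = sse))
  }
  if (is.null(best)) {
    warning(sprintf("%s NPQ fit failed to converge", phase))
    return(new("NPQFit", phase = phase, a = NA_real_, b = NA_real_,
               c = NA_real_, rmse = NA_real_, converged = FALSE))
  }
  new("NPQFit", phase = phase, a = best$a, b = best$b,
      c = if (phase == "induction") NA_real_ else best$c,
      rmse = sqrt(best$sse / length(tt)), converged = TRUE)
}

#' Fit the exponential NPQ induction model
#'
#' Unweighted nonlinear least squares of
#' \eqn{NPQ = a (1 - e^{-b t})} to the induction-phase pulses, with
#' a, b >= 0 enforced by bounds; a is initialised at the last observed NPQ
#' and b from a log-linearised regression over the first half of the
#' pulses, with deterministic jittered restarts.
#'
#' @param trace A \linkS4class{FluorTrace} with at least 4 induction
#'   pulses.
#' @return An \linkS4class{NPQFit} (phase "induction", no offset c).
#' @examples
#' tr <- generateNpqTrace(noiseSd = 0, seed = 1)
#' fitInduction(tr)
#' @export
fitInduction <- function(trace) {
  d <- .npqOfPhase(trace, "induction")
  .fitNpqPhase(d$t, d$npq, "induction")
}

#' Fit the exponential NPQ relaxation model
#'
#' Unweighted nonlinear least squares of
#' \eqn{NPQ = a e^{-b t} + c} to the relaxation-phase pulses (t re-zeroed
#' at light-off), with a, b >= 0 and c unconstrained in sign: c captures
#' sustained quenching that does not relax in the dark.
#'
#' @param trace A \linkS4class{FluorTrace} with at least 4 relaxation
#'   pulses.
#' @return An \linkS4class{NPQFit} (phase "relaxation").
#' @export
fitRelaxation <- function(trace) {
  d <- .npqOfPhase(trace, "relaxation")
  .fitNpqPhase(d$t, d$npq, "relaxation")
}

#' Maximum NPQ of a trace
#'
#' Defined as the maximum observed NPQ across the induction-phase pulses
#' (robust when induction has not plateaued, and equal to any transient
#' overshoot by construction) rather than the fitted amplitude.
#'
#' @param trace A \linkS4class{FluorTrace} with at least one induction
#'   pulse.
#' @return Maximum induction-phase NPQ.
#' @export
maxNpq <- function(trace) {
  d <- .npqOfPhase(trace, "induction")
  if (nrow(d) == 0L) stop("trace has no induction pulses")
  max(d$npq)
}

#' Summarise one fluorescence trace
#'
#' Fv/Fm, induction and relaxation fits and maximum NPQ, as a one-row
#' data.frame (the per-leaf scalar traits used by downstream inference).
#'
#' @param trace A \linkS4class{FluorTrace}.
#' @return One-row data.frame with columns \code{leaf_id},
#'   \code{instrument}, \code{fvfm}, \code{a_ind}, \code{b_ind},
#'   \code{a_rel}, \code{b_rel}, \code{c_rel}, \code{max_npq},
#'   \code{converged}.
#' @export
summariseNpqTrace <- function(trace) {
  ind <- fitInduction(trace)
  rel <- fitRelaxation(trace)
  data.frame(
    leaf_id = trace@leafId, instrument = trace@instrument,
    fvfm = computeFvFm(trace@FmDark, trace@Fo),
    a_ind = ind@a, b_ind = ind@b,
    a_rel = rel@a, b_rel = rel@b, c_rel = rel@c,
    max_npq = maxNpq(trace),
    converged = isConverged(ind) && isConverged(rel)
  )
}
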