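## A/ci curve fitting: C3 bilinear FvCB and C4 initial-slope + hyperbola.

#' Fit the FvCB model with bilinear transition-point estimation
#'
#' Points are sorted by ci and every candidate split with at least three
#' points per segment is evaluated: over the lower (Rubisco-limited)
#' segment, ordinary least squares of A on
#' \eqn{x_1 = (c_i - \Gamma^*)/(c_i + K_m)} yields (Vcmax, Rd); over the
#' upper (RuBP-regeneration-limited) segment, least squares of (A + Rd) on
#' \eqn{x_2 = (c_i - \Gamma^*)/(4 c_i + 8 \Gamma^*)} with Rd held at the
#' lower-segment estimate yields Jmax. The split minimising the full-curve
#' SSE against min(Ac, Aj) - Rd is selected (ties broken towards the
#' smaller split index), and the transition ci is reported as the midpoint
#' between the two ci values straddling that split.
#'
#' A final refinement pass reassigns each point to the limitation branch
#' the current fit says is active (under the min() rule, points below the
#' compensation point are RuBP-limited even though they sit at the low-ci
#' end) and solves the joint least-squares problem in (Vcmax, Jmax, Rd)
#' for that assignment, iterating from every admissible split. The
#' refinement is kept only when it lowers the SSE, so the reported fit
#' never does worse than the plain split search and closely approaches the
#' global least-squares optimum of the min() model.
#'
#' Degenerate inputs for which no candidate split yields positive Vcmax and
#' Jmax are flagged as failed fits (with a warning), never silently
#' returned.
#'
#' @param curve An \linkS4class{ACiCurve} with at least 6 points.
#' @param constants A \linkS4class{KineticConstants} object.
#' @return An \linkS4class{FvCBFit}.
#' @examples
#' curve <- generateAciC3(noiseSd = 0, ciJitterSd = 0, seed = 1)
#' fitFvcbBilinear(curve)
#' @export
fitFvcbBilinear <- function(curve, constants = kineticConstants()) {
  pts <- aciPoints(curve)
  n <- nrow(pts)
  if (n < 6L) stop("bilinear FvCB fit requires at least 6 points")
  ord <- order(pts$ci)
  ci <- pts$ci[ord]
  A <- pts$A[ord]
  g <- constants@gammastar
  Km <- kmOf(constants)
  x1 <- (ci - g) / (ci + Km)
  x2 <- (ci - g) / (4 * ci + 8 * g)

  best <- NULL
  for (k in 3:(n - 3)) {
    lo <- seq_len(k)
    hi <- (k + 1):n
    fitLo <- stats::lm.fit(cbind(1, x1[lo]), A[lo])
    Vcmax <- unname(fitLo$coefficients[2L])
    Rd <- -unname(fitLo$coefficients[1L])
    if (!is.finite(Vcmax) || Vcmax <= 0) next
    denom <- sum(x2[hi]^2)
    if (denom <= 0) next
    Jmax <- sum((A[hi] + Rd) * x2[hi]) / denom
    if (!is.finite(Jmax) || Jmax <= 0) next
    pred <- pmin(Vcmax * x1, Jmax * x2) - Rd
    sse <- sum((A - pred)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(k = k, Vcmax = Vcmax, Jmax = Jmax, Rd = Rd, sse = sse)
    }
  }
  if (is.null(best)) {
    warning("bilinear FvCB fit failed: no split yields positive Vcmax and Jmax")
    return(new("FvCBFit", Vcmax = NA_real_, Jmax = NA_real_, Rd = NA_real_,
               transitionCi = NA_real_, sse = NA_real_, nPoints = n,
               converged = FALSE))
  }

  ## refinement pass. Two reasons the plain split search is not the least-
  ## squares optimum of the min() model: (i) a ci-ordered split assigns every
  ## low-ci point to the Rubisco branch, but under the min() rule points
  ## below the compensation point are RuBP-limited; (ii) the two-stage
  ## estimate does not share Rd across the two segments. Starting from each
  ## admissible split's estimates, iterate: assign each point to the branch
  ## the current parameters say is limiting, then solve the joint linear
  ## least-squares problem A = Vcmax x1 [Ac] + Jmax x2 [Aj] - Rd for
  ## (Vcmax, Jmax, Rd) given that assignment. The best refinement is kept
  ## only when it lowers the full-curve SSE.
  cur <- best
  for (k in 3:(n - 3)) {
    start <- list(Vcmax = best$Vcmax, Jmax = best$Jmax, Rd = best$Rd)
    if (k != best$k) {
      fitLo <- stats::lm.fit(cbind(1, x1[seq_len(k)]), A[seq_len(k)])
      Vc0 <- unname(fitLo$coefficients[2L])
      Rd0 <- -unname(fitLo$coefficients[1L])
      if (!is.finite(Vc0) || Vc0 <= 0) next
      hi <- (k + 1):n
      Jm0 <- sum((A[hi] + Rd0) * x2[hi]) / sum(x2[hi]^2)
      if (!is.finite(Jm0) || Jm0 <= 0) next
      start <- list(Vcmax = Vc0, Jmax = Jm0, Rd = Rd0)
    }
    for (iter in 1:20) {
      acLim <- start$Vcmax * x1 <= start$Jmax * x2
      if (sum(acLim) < 2L || sum(!acLim) < 1L) break
      X <- cbind(x1 * acLim, x2 * !acLim, -1)
      fit <- stats::lm.fit(X, A)
      Vc <- unname(fit$coefficients[1L])
      Jm <- unname(fit$coefficients[2L])
      Rd <- unname(fit$coefficients[3L])
      if (!is.finite(Vc) || Vc <= 0 || !is.finite(Jm) || Jm <= 0) break
      sse <- sum((A - (pmin(Vc * x1, Jm * x2) - Rd))^2)
      if (sse < cur$sse - 1e-12)
        cur <- list(k = cur$k, Vcmax = Vc, Jmax = Jm, Rd = Rd, sse = sse)
      newStart <- list(Vcmax = Vc, Jmax = Jm, Rd = Rd)
      if (identical(acLim, newStart$Vcmax * x1 <= newStart$Jmax * x2)) break
      start <- newStart
    }
  }

  new("FvCBFit", Vcmax = cur$Vcmax, Jmax = cur$Jmax, Rd = cur$Rd,
      transitionCi = (ci[best$k] + ci[best$k + 1L]) / 2,
      sse = cur$sse, nPoints = n, converged = TRUE)
}

#' Estimate Vpmax from the initial slope of a C4 A/ci curve
#'
#' Least-squares fit of the PEPc-limited model
#' \eqn{A = V_{pmax} c_i / (c_i + K_p) - R_d} to the low-ci subset
#' (\code{ci <= ciCutoff}) with Kp held fixed: with Kp fixed the model is
#' linear in (Vpmax, Rd), so the least-squares solution is computed exactly
#' by ordinary regression of A on \eqn{c_i/(c_i + K_p)}.
#'
#' The default cutoff of 100 umol mol-1 captures the low-CO2 descending
#' steps of the C4 measurement sequence; Kp defaults to 80 umol mol-1
#' because the sparse low-ci design cannot identify it jointly.
#'
#' @param curve An \linkS4class{ACiCurve}.
#' @param ciCutoff Upper ci bound for the initial-slope subset
#'   (umol mol-1).
#' @param KpFixed Fixed PEPc Michaelis constant (umol mol-1).
#' @return List with components \code{Vpmax}, \code{RdSlope}, \code{sse},
#'   \code{n} and \code{converged}; a non-positive fitted Vpmax (e.g. all
#'   qualifying A identical) is flagged \code{converged = FALSE} with a
#'   warning.
#' @export
fitVpmax <- function(curve, ciCutoff = 100, KpFixed = 80) {
  pts <- aciPoints(curve)
  sel <- pts$ci <= ciCutoff
  if (sum(sel) < 3L)
    stop(sprintf("Vpmax fit failed: only %d point(s) with ci <= %g (need >= 3)",
                 sum(sel), ciCutoff))
  ci <- pts$ci[sel]
  A <- pts$A[sel]
  x <- ci / (ci + KpFixed)
  fit <- stats::lm.fit(cbind(1, x), A)
  Vpmax <- unname(fit$coefficients[2L])
  Rd <- -unname(fit$coefficients[1L])
  sse <- sum(fit$residuals^2)
  if (!is.finite(Vpmax) || Vpmax <= 0) {
    warning("Vpmax fit degenerate: non-positive initial slope")
    return(list(Vpmax = NA_real_, RdSlope = NA_real_, sse = sse,
                n = length(ci), converged = FALSE))
  }
  list(Vpmax = Vpmax, RdSlope = Rd, sse = sse, n = length(ci),
       converged = TRUE)
}

## deterministic multiplicative jitters for multi-start NLS
.nrhJitters <- rbind(
  c(1.00, 1.00, 1.00, 1.00),
  c(0.60, 1.05, 0.50, 1.00),
  c(1.60, 0.95, 1.30, 1.00),
  c(0.80, 1.15, 0.90, 0.50),
  c(1.25, 0.90, 1.10, 1.50)
)

#' Fit a four-parameter non-rectangular hyperbola to an A/ci curve
#'
#' Nonlinear least squares of [nonRectHyperbola()] with parameters
#' (phi, Asat, theta, offset). The reported Amax is the horizontal
#' asymptote of the fitted function, \code{Asat + offset}. Initialisation:
#' phi from the slope of the two lowest-ci points, Asat at 1.1 x max(A),
#' theta at 0.7 and offset at min(0, min(A)), with five deterministic
#' jittered restarts; the restart with the lowest SSE wins. theta
#' converging onto a bound is flagged via \code{thetaPinned}.
#'
#' @param curve An \linkS4class{ACiCurve} with at least 6 points spanning
#'   low and saturating ci.
#' @param thetaBounds Lower/upper bounds for theta.
#' @param KpFixed Recorded in the result for provenance (the hyperbola fit
#'   itself does not use Kp).
#' @return A \linkS4class{C4Fit} with the hyperbola fields populated
#'   (\code{Vpmax}, \code{RdSlope} are NA; see [fitC4Curve()] for the
#'   combined fit).
#' @export
fitNrhAmax <- function(curve, thetaBounds = c(0.01, 0.999), KpFixed = 80) {
  pts <- aciPoints(curve)
  if (nrow(pts) < 6L)
    stop("non-rectangular hyperbola fit requires at least 6 points")
  ord <- order(pts$ci)
  ci <- pts$ci[ord]
  A <- pts$A[ord]
  slope0 <- (A[2L] - A[1L]) / (ci[2L] - ci[1L])
  if (!is.finite(slope0) || slope0 <= 0) slope0 <- 0.3
  start0 <- c(phi = slope0, Asat = 1.1 * max(A), theta = 0.7,
              offset = min(0, min(A)))
  lower <- c(phi = 1e-4, Asat = 1e-3, theta = thetaBounds[1L],
             offset = -Inf)
  upper <- c(phi = Inf, Asat = Inf, theta = thetaBounds[2L], offset = Inf)
  df <- data.frame(ci = ci, A = A)

  best <- NULL
  for (j in seq_len(nrow(.nrhJitters))) {
    st <- start0 * .nrhJitters[j, ]
    st["offset"] <- start0["offset"] * .nrhJitters[j, 4L] -
      (j - 1) * 0.2                      # shift, since offset may be 0
    st <- pmin(pmax(st, lower + 1e-6), c(Inf, Inf, upper[3L] - 1e-6, Inf))
    fit <- tryCatch(
      nlsLM(A ~ nonRectHyperbola(ci, phi, Asat, theta, offset),
            data = df, start = as.list(st),
            lower = lower, upper = upper,
            control = nls.lm.control(maxiter = 200, ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- c(as.list(coef(fit)), list(sse = sse))
    }
  }
  if (is.null(best)) {
    warning("non-rectangular hyperbola fit failed to converge from all starts")
    return(new("C4Fit", Vpmax = NA_real_, Kp = KpFixed, RdSlope = NA_real_,
               Amax = NA_real_, phi = NA_real_, theta = NA_real_,
               offset = NA_real_, sse = NA_real_, thetaPinned = FALSE,
               converged = FALSE))
  }
  pinned <- min(abs(best$theta - thetaBounds)) < 1e-6
  if (pinned)
    warning(sprintf("theta pinned at bound (%.4g)", best$theta))
  new("C4Fit", Vpmax = NA_real_, Kp = KpFixed, RdSlope = NA_real_,
      Amax = best$Asat + best$offset, phi = best$phi, theta = best$theta,
      offset = best$offset, sse = best$sse, thetaPinned = pinned,
      converged = TRUE)
}

#' Full C4 capacity fit: initial-slope Vpmax plus hyperbola Amax
#'
#' Convenience wrapper running [fitVpmax()] on the low-ci subset and
#' [fitNrhAmax()] on the whole curve, combining both into a single
#' \linkS4class{C4Fit} (sse = slope-subset SSE + hyperbola SSE).
#'
#' @inheritParams fitVpmax
#' @inheritParams fitNrhAmax
#' @return A \linkS4class{C4Fit}.
#' @export
fitC4Curve <- function(curve, ciCutoff = 100, KpFixed = 80,
                       thetaBounds = c(0.01, 0.999)) {
  vp <- fitVpmax(curve, ciCutoff = ciCutoff, KpFixed = KpFixed)
  nrh <- fitNrhAmax(curve, thetaBounds = thetaBounds, KpFixed = KpFixed)
  new("C4Fit", Vpmax = vp$Vpmax, Kp = KpFixed, RdSlope = vp$RdSlope,
      Amax = nrh@Amax, phi = nrh@phi, theta = nrh@theta,
      offset = nrh@offset, sse = vp$sse + nrh@sse,
      thetaPinned = nrh@thetaPinned,
      converged = vp$converged && nrh@converged)
}
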