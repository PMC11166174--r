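## K_H estimation: when the plasma input is negligible and CO2 efflux is
## much faster than hydrolysis, the late tissue TAC decays as a single
## exponential whose rate is the hydrolysis rate of the covalent complex.
## The estimator is a nonlinear least-squares mono-exponential fit on the
## late washout window (default 15-90 min), with time in hours so the
## fitted rate is directly in 1/h.

#' Fit a mono-exponential washout to a TAC
#'
#' Least-squares fit of Radioactivity(t) = A exp(-a t) to frame values
#' whose midpoints fall inside the window, with t in hours; the fitted
#' rate a is reported as the hydrolysis rate K_H (1/h) under the
#' fast-CO2-efflux approximation. Initialization uses a log-linear
#' regression on the positive in-window values; the rate is bounded to
#' [0, 20] 1/h, so flat data degenerate cleanly to a = 0.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param window fit window in min, default c(15, 90).
#' @param weights optional per-frame weights; \code{"duration"} weights
#'   proportionally to frame duration, NULL (default) uses the TAC's own
#'   weights if set, else uniform.
#' @return A [MonoExpFit-class]; if the optimizer fails the convergence
#'   flag is FALSE and parameters are NA.
#' @examples
#' sched <- defaultFrameSchedule()
#' tac <- timeActivityCurve(sched, 1.5 * exp(-0.69 * frameMidpoints(sched) / 60))
#' khValue(fitMonoExp(tac))
#' @export
fitMonoExp <- function(tac, window = c(15, 90), weights = NULL) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (length(window) != 2L || diff(window) <= 0)
    stop("window must be c(start, end) with start < end (min)")
  mid <- frameMidpoints(tac@schedule)
  sel <- mid >= window[1L] & mid <= window[2L]
  if (sum(sel) < 3L)
    stop("need at least 3 frames with midpoints inside the fit window")
  th <- mid[sel] / 60
  y <- tac@values[sel]
  w <- if (identical(weights, "duration")) {
    frameDurations(tac@schedule)[sel]
  } else if (is.numeric(weights)) {
    if (length(weights) == nFrames(tac@schedule)) weights[sel]
    else if (length(weights) == sum(sel)) weights
    else stop("numeric weights must be per frame or per in-window frame")
  } else if (length(tac@weights)) {
    tac@weights[sel]
  } else rep(1, sum(sel))

  ## log-linear initializer on positive values (noise can push frames <= 0;
  ## those are kept for the NLS but excluded here)
  pos <- y > 0
  if (sum(pos) >= 2L) {
    lf <- stats::lm.wfit(cbind(1, th[pos]), log(y[pos]), w[pos])
    a0 <- min(max(-lf$coefficients[2L], 0), 20)
    A0 <- if (y[1L] > 0) y[1L] else exp(lf$coefficients[1L])
  } else {
    a0 <- 0
    A0 <- max(mean(y), 1e-6)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-a * th),
                      start = list(A = max(A0, 1e-12), a = a0),
                      lower = c(A = 0, a = 0), upper = c(A = Inf, a = 20),
                      weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("MonoExpFit", amplitude = NA_real_, rate = NA_real_,
               window = as.numeric(window), residualNorm = NA_real_,
               converged = FALSE, nPoints = sum(sel)))
  }
  cf <- stats::coef(fit)
  new("MonoExpFit", amplitude = unname(cf["A"]), rate = unname(cf["a"]),
      window = as.numeric(window),
      residualNorm = sqrt(sum(w * stats::resid(fit)^2)),
      converged = TRUE, nPoints = sum(sel))
}

#' Normalize a TAC to a reference frame
#'
#' Rescales frame values so that the frame containing the reference time
#' equals 100 (percent of the reference activity). Normalization leaves
#' the fitted washout rate unchanged (the amplitude absorbs the scale).
#'
#' @param tac a [TimeActivityCurve-class].
#' @param referenceTime time (min) identifying the reference frame;
#'   default 15.
#' @return A normalized [TimeActivityCurve-class] with units
#'   "percent_max".
#' @export
normalizeToReference <- function(tac, referenceTime = 15) {
  stopifnot(is(tac, "TimeActivityCurve"))
  s <- frameStarts(tac@schedule); e <- frameEnds(tac@schedule)
  idx <- which(s <= referenceTime & referenceTime < e)
  if (!length(idx)) {
    if (abs(referenceTime - e[length(e)]) < 1e-9) idx <- length(e)
    else stop("referenceTime falls outside the schedule")
  }
  ref <- tac@values[idx[1L]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference frame value must be positive")
  timeActivityCurve(tac@schedule, 100 * tac@values / ref,
                    units = "percent_max", weights = tac@weights)
}

#' Ipsilateral/contralateral hydrolysis-rate ratio
#'
#' @param khIps ipsilateral K_H (1/h).
#' @param khCont contralateral K_H (1/h), > 0.
#' @return khIps / khCont.
#' @examples
#' ipsContRatio(0.41, 0.62)
#' @export
ipsContRatio <- function(khIps, khCont) {
  if (!is.finite(khCont) || khCont <= 0)
    stop("contralateral K_H must be positive")
  khIps / khCont
}

#' Percent reduction of the ipsilateral hydrolysis rate
#'
#' @param khIps ipsilateral K_H (1/h).
#' @param khCont contralateral K_H (1/h), > 0.
#' @return 100 (1 - khIps/khCont), in percent.
#' @examples
#' percentReduction(0.41, 0.62)
#' @export
percentReduction <- function(khIps, khCont) {
  100 * (1 - ipsContRatio(khIps, khCont))
}
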