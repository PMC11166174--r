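## Compartment model of a hydrolyzable covalent probe in tissue:
##   dC1/dt = K1 Cp(t) - (k2 + k3) C1
##   dC2/dt = k3 C1 - kH C2            (kH = KH/60, 1/min)
##   dC3/dt = kH C2 - k5 C3 + k4 CpCO2(t)
## The system is linear with biexponential forcing, so it is integrated
## exactly: each forcing exponential becomes an augmented state with
## du/dt = -lambda u, and the full homogeneous system is propagated by a
## matrix exponential between breakpoints (delays, rate-switch events) and
## output times. This sidesteps stiffness from k5 >> kH entirely.

.buildSystemMatrix <- function(rates, nCo2 = 0L, lambdaCo2 = numeric(0),
                               input) {
  kh <- kHPerMin(rates)
  n <- 5L + nCo2
  M <- matrix(0, n, n)
  ## tissue block
  M[1L, 1L] <- -(rates@k2 + rates@k3)
  M[2L, 1L] <- rates@k3
  M[2L, 2L] <- -kh
  M[3L, 2L] <- kh
  M[3L, 3L] <- -rates@k5
  ## probe input forcing states u1, u2 (amplitudes folded into the state)
  M[1L, 4L] <- rates@K1
  M[1L, 5L] <- rates@K1
  M[4L, 4L] <- -input@lambda1
  M[5L, 5L] <- -input@lambda2
  if (nCo2 == 2L) {
    M[3L, 6L] <- rates@k4
    M[3L, 7L] <- rates@k4
    M[6L, 6L] <- -lambdaCo2[1L]
    M[7L, 7L] <- -lambdaCo2[2L]
  }
  M
}

.expmStep <- function(M, dt, x) {
  if (dt == 0) return(x)
  as.numeric(Matrix::expm(Matrix::Matrix(M * dt)) %*% x)
}

.validateEvents <- function(events) {
  for (ev in events) {
    if (!is.list(ev) || is.null(ev$time) || is.null(ev$rates))
      stop("each event must be list(time =, rates =)")
    if (!is(ev$rates, "RateConstants")) stop("event rates must be RateConstants")
  }
  events[order(vapply(events, `[[`, numeric(1), "time"))]
}

## Core propagator: evaluates (C1, C2, C3) at arbitrary non-negative times
## (not necessarily starting at 0); used by both the public solver and the
## exact frame-averaging path.
.solveAt <- function(rates, input, times, initial = c(0, 0, 0),
                     co2Input = NULL, events = list()) {
  stopifnot(all(times >= 0), !is.unsorted(times, strictly = FALSE))
  events <- .validateEvents(events)
  nCo2 <- if (is.null(co2Input)) 0L else 2L
  lamCo2 <- if (nCo2) c(co2Input@lambda1, co2Input@lambda2) else numeric(0)

  ## breakpoints where the augmented state jumps or the matrix changes
  jumps <- list()
  if (input@delay >= 0)
    jumps[[length(jumps) + 1L]] <- list(time = input@delay, kind = "u",
                                        value = c(input@A1, input@A2))
  if (nCo2)
    jumps[[length(jumps) + 1L]] <- list(time = co2Input@delay, kind = "v",
                                        value = c(co2Input@A1, co2Input@A2))
  for (ev in events)
    jumps[[length(jumps) + 1L]] <- list(time = ev$time, kind = "rates",
                                        value = ev$rates)
  jumps <- jumps[order(vapply(jumps, `[[`, numeric(1), "time"))]

  x <- c(initial, rep(0, 2L + nCo2))
  cur <- rates
  M <- .buildSystemMatrix(cur, nCo2, lamCo2, input)
  tNow <- 0
  ji <- 1L
  out <- matrix(0, nrow = length(times), ncol = 3L)

  for (i in seq_along(times)) {
    tTarget <- times[i]
    while (ji <= length(jumps) && jumps[[ji]]$time <= tTarget) {
      jp <- jumps[[ji]]
      x <- .expmStep(M, jp$time - tNow, x)
      tNow <- jp$time
      if (jp$kind == "u") {
        x[4L:5L] <- x[4L:5L] + jp$value
      } else if (jp$kind == "v") {
        x[6L:7L] <- x[6L:7L] + jp$value
      } else {
        cur <- jp$value
        M <- .buildSystemMatrix(cur, nCo2, lamCo2, input)
      }
      ji <- ji + 1L
    }
    x <- .expmStep(M, tTarget - tNow, x)
    tNow <- tTarget
    out[i, ] <- x[1L:3L]
  }
  out
}

#' Solve the tissue compartment model
#'
#' Integrates the linear three-tissue-pool model (free probe, covalent
#' complex, tissue CO2) driven by a plasma input function. The solution is
#' exact for piecewise-constant rates with biexponential forcing: the
#' forcing exponentials are augmented into the state vector and the
#' homogeneous system is propagated by matrix exponentials, so the fast
#' CO2 efflux (k5 of order 1/min) causes no stiffness problems.
#'
#' @param rates a [RateConstants-class].
#' @param input an [InputFunction-class] (plasma probe curve).
#' @param times strictly increasing output grid (min) starting at 0.
#' @param initial initial concentrations c(C1, C2, C3); default all zero
#'   (tracer injected at t = 0).
#' @param co2Input optional second [InputFunction-class] for the plasma
#'   CO2 pool, enabling k4 > 0; default NULL (k4 pathway inert).
#' @param events optional list of rate-switch events, each
#'   \code{list(time =, rates =)}, for chase/blocking designs. Rates are
#'   piecewise constant between events.
#' @return A [CompartmentCurves-class] on \code{times}.
#' @examples
#' r <- rateConstants(K1 = 0.15, k2 = 0.3, k3 = 0.6, KH = 0.66)
#' cc <- solveCompartments(r, inputFunction(), seq(0, 90, by = 1))
#' max(totalActivity(cc))
#' @export
solveCompartments <- function(rates, input, times, initial = c(0, 0, 0),
                              co2Input = NULL, events = list()) {
  stopifnot(is(rates, "RateConstants"), is(input, "InputFunction"))
  validObject(rates)
  if (length(times) < 1L || any(!is.finite(times)))
    stop("times must be a finite numeric grid")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (abs(times[1L]) > 1e-12) stop("time grid must start at 0")
  if (length(initial) != 3L || any(initial < 0))
    stop("initial must be three non-negative concentrations")
  vals <- .solveAt(rates, input, times, initial, co2Input, events)
  ## exact solution of a positive system: clamp the vanishing negative
  ## round-off so the non-negativity contract holds exactly
  vals[vals < 0 & vals > -1e-12] <- 0
  new("CompartmentCurves", time = as.numeric(times),
      C1 = vals[, 1L], C2 = vals[, 2L], C3 = vals[, 3L])
}

## ---------------------------------------------------------------------------
## Frame averaging
## ---------------------------------------------------------------------------

.glCache <- new.env(parent = emptyenv())

.glNodes <- function(n = 10L) {
  key <- as.character(n)
  if (is.null(.glCache[[key]]))
    .glCache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .glCache[[key]]
}

## Gauss-Legendre nodes/weights mapped onto each frame; 10 points per
## frame resolves an exponential over a 5-min frame to machine precision.
.frameQuadrature <- function(schedule, n = 10L) {
  gl <- .glNodes(n)
  s <- frameStarts(schedule); e <- frameEnds(schedule)
  nodes <- outer(gl$x, (e - s) / 2) + rep((s + e) / 2, each = n)
  weights <- outer(gl$w, (e - s) / 2)
  list(nodes = nodes, weights = weights)  # n x nFrames matrices
}

#' Average a continuous curve over acquisition frames
#'
#' Computes, for every frame, the duration-normalized integral of the
#' activity curve over the frame interval, turning continuous model output
#' into frame-binned PET measurements. Integration uses 10-point
#' Gauss-Legendre quadrature per frame (exact for polynomials to degree
#' 19; machine precision for the model's exponentials).
#'
#' @param x a function of time (min), or a [CompartmentCurves-class]
#'   (whose total activity is interpolated by a natural cubic spline on
#'   its grid before integration).
#' @param schedule a [FrameSchedule-class].
#' @param units units tag for the returned curve.
#' @return A [TimeActivityCurve-class].
#' @examples
#' frameAverage(function(t) exp(-0.05 * t), defaultFrameSchedule())
#' @export
setGeneric("frameAverage",
           function(x, schedule, units = "SUV") standardGeneric("frameAverage"))

#' @rdname frameAverage
#' @export
setMethod("frameAverage", "function", function(x, schedule, units = "SUV") {
  if (!is(schedule, "FrameSchedule") || nFrames(schedule) == 0L)
    stop("schedule must be a non-empty FrameSchedule")
  q <- .frameQuadrature(schedule)
  fv <- matrix(x(as.numeric(q$nodes)), nrow = nrow(q$nodes))
  vals <- colSums(fv * q$weights) / frameDurations(schedule)
  timeActivityCurve(schedule, vals, units = units)
})

#' @rdname frameAverage
#' @export
setMethod("frameAverage", "CompartmentCurves",
          function(x, schedule, units = "SUV") {
  f <- stats::splinefun(x@time, totalActivity(x), method = "natural")
  frameAverage(f, schedule, units = units)
})

## Exact frame-averaged model TAC: evaluates the closed-form solution at
## the quadrature nodes themselves, so no interpolation error enters.
.frameAverageModel <- function(rates, input, schedule, co2Input = NULL,
                               events = list(), initial = c(0, 0, 0)) {
  q <- .frameQuadrature(schedule)
  nodes <- as.numeric(q$nodes)
  ord <- order(nodes)
  vals <- .solveAt(rates, input, nodes[ord], initial, co2Input, events)
  tot <- numeric(length(nodes))
  tot[ord] <- rowSums(vals)
  fv <- matrix(tot, nrow = nrow(q$nodes))
  timeActivityCurve(schedule,
                    colSums(fv * q$weights) / frameDurations(schedule))
}

## ---------------------------------------------------------------------------
## SUV and decay correction
## ---------------------------------------------------------------------------

#' Standardized uptake value
#'
#' SUV = concentration / (injected dose / body weight); dimensionless when
#' concentration and dose/weight share units (e.g. kBq/ml over kBq/g).
#'
#' @param concentration tissue concentration(s).
#' @param injectedDose injected dose (> 0).
#' @param bodyWeight body weight (> 0).
#' @return SUV value(s).
#' @export
toSUV <- function(concentration, injectedDose, bodyWeight) {
  if (!is.finite(injectedDose) || injectedDose <= 0)
    stop("injectedDose must be positive")
  if (!is.finite(bodyWeight) || bodyWeight <= 0)
    stop("bodyWeight must be positive")
  concentration / (injectedDose / bodyWeight)
}

#' Physical decay correction of a TAC
#'
#' Rescales frame values to a reference time using the isotope half-life:
#' each frame is multiplied by 2^((t_mid - reference)/halfLife). With
#' \code{invert = TRUE} the correction is undone exactly.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param halfLife isotope half-life (min); default 20.4 (carbon-11).
#' @param referenceTime time the values are corrected to (min); default 0,
#'   the injection time.
#' @param invert undo a previous correction.
#' @return A corrected [TimeActivityCurve-class].
#' @export
decayCorrect <- function(tac, halfLife = 20.4, referenceTime = 0,
                         invert = FALSE) {
  stopifnot(is(tac, "TimeActivityCurve"))
  if (!is.finite(halfLife) || halfLife <= 0) stop("halfLife must be positive")
  fac <- 2^((frameMidpoints(tac@schedule) - referenceTime) / halfLife)
  if (invert) fac <- 1 / fac
  timeActivityCurve(tac@schedule, tac@values * fac, units = tac@units,
                    weights = tac@weights)
}
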