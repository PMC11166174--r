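#' @import methods
NULL

## ---------------------------------------------------------------------------
## FrameSchedule
## ---------------------------------------------------------------------------

#' Dynamic-scan frame schedule
#'
#' Ordered acquisition time bins of a dynamic PET scan, in minutes post
#' injection. Frames must be contiguous and non-overlapping with positive
#' durations.
#'
#' @slot start numeric vector of frame start times (min).
#' @slot end numeric vector of frame end times (min).
#'
#' @seealso [frameSchedule()], [defaultFrameSchedule()]
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", end = "numeric"),
  validity = function(object) {
    s <- object@start; e <- object@end
    if (length(s) != length(e)) return("start and end must have equal length")
    if (length(s) == 0L) return("schedule must contain at least one frame")
    if (any(!is.finite(s)) || any(!is.finite(e))) return("frame times must be finite")
    if (any(e - s <= 0)) return("all frame durations must be positive")
    if (length(s) > 1L && any(abs(s[-1L] - e[-length(e)]) > 1e-9))
      return("frames must be contiguous (each start equals the previous end)")
    TRUE
  }
)

#' Construct a frame schedule
#'
#' @param start,end numeric vectors of frame start/end times in minutes.
#' @return A [FrameSchedule-class] object.
#' @examples
#' frameSchedule(c(0, 1, 2), c(1, 2, 4))
#' @export
frameSchedule <- function(start, end) {
  new("FrameSchedule", start = as.numeric(start), end = as.numeric(end))
}

#' Default 90-min acquisition schedule
#'
#' The 26-frame schedule used throughout: 4 x 1 min, 8 x 2 min,
#' 14 x 5 min, spanning 0--90 min.
#'
#' @return A [FrameSchedule-class] with 26 frames.
#' @export
defaultFrameSchedule <- function() {
  dur <- c(rep(1, 4), rep(2, 8), rep(5, 14))
  end <- cumsum(dur)
  frameSchedule(start = end - dur, end = end)
}

#' @describeIn frameSchedule Number of frames.
#' @param schedule a [FrameSchedule-class].
#' @export
nFrames <- function(schedule) length(schedule@start)

#' @describeIn frameSchedule Frame start times (min).
#' @export
frameStarts <- function(schedule) schedule@start

#' @describeIn frameSchedule Frame end times (min).
#' @export
frameEnds <- function(schedule) schedule@end

#' @describeIn frameSchedule Frame midpoint times (min).
#' @export
frameMidpoints <- function(schedule) (schedule@start + schedule@end) / 2

#' @describeIn frameSchedule Frame durations (min).
#' @export
frameDurations <- function(schedule) schedule@end - schedule@start

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.4g - %.4g min\n",
              nFrames(object), object@start[1L], object@end[nFrames(object)]))
})

## ---------------------------------------------------------------------------
## RateConstants
## ---------------------------------------------------------------------------

#' Kinetic rate constants of the tissue compartment model
#'
#' Rates of the linear tissue model for a hydrolyzable covalent probe:
#' plasma -> free tissue probe (K1), free-probe efflux (k2), covalent
#' association to the target enzyme (k3), hydrolysis of the covalent
#' complex (KH, stored in 1/h as conventionally reported), CO2 reuptake
#' from plasma (k4) and CO2 efflux from tissue (k5).
#'
#' All rates except KH are in 1/min; KH is in 1/h and converted internally
#' (divide by 60) when integrating.
#'
#' @slot K1 delivery rate, ml/ml/min (acts as 1/min scaling of Cp).
#' @slot k2 free-probe efflux rate, 1/min.
#' @slot k3 association rate to the enzyme, 1/min.
#' @slot KH hydrolysis rate of the covalent complex, 1/h.
#' @slot k4 CO2 reuptake rate from plasma, 1/min.
#' @slot k5 CO2 efflux rate from tissue, 1/min.
#'
#' @export
setClass("RateConstants",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 KH = "numeric", k4 = "numeric", k5 = "numeric"),
  validity = function(object) {
    v <- c(K1 = object@K1, k2 = object@k2, k3 = object@k3,
           KH = object@KH, k4 = object@k4, k5 = object@k5)
    if (length(v) != 6L || any(!is.finite(v)))
      return("all six rates must be finite scalars")
    if (any(v < 0)) return(sprintf("negative rate(s): %s",
                                   paste(names(v)[v < 0], collapse = ", ")))
    TRUE
  }
)

#' Construct kinetic rate constants
#'
#' @param K1 delivery rate (1/min scaling of the plasma curve).
#' @param k2 free-probe efflux rate (1/min).
#' @param k3 covalent association rate (1/min).
#' @param KH hydrolysis rate of the complex, in 1/h.
#' @param k4 CO2 reuptake rate from plasma (1/min); default 0 (the CO2
#'   plasma pool is rarely measured).
#' @param k5 CO2 efflux rate from tissue (1/min); default 1.74, the
#'   reported CO2 washout rate in healthy human brain.
#' @return A [RateConstants-class] object.
#' @examples
#' rateConstants(K1 = 0.15, k2 = 0.3, k3 = 0.6, KH = 0.66)
#' @export
rateConstants <- function(K1, k2, k3, KH, k4 = 0, k5 = 1.74) {
  new("RateConstants", K1 = as.numeric(K1), k2 = as.numeric(k2),
      k3 = as.numeric(k3), KH = as.numeric(KH), k4 = as.numeric(k4),
      k5 = as.numeric(k5))
}

#' Hydrolysis rate in 1/min
#'
#' @param rates a [RateConstants-class].
#' @return KH converted from 1/h to 1/min (KH/60).
#' @export
kHPerMin <- function(rates) rates@KH / 60

setMethod("show", "RateConstants", function(object) {
  cat(sprintf(
    "RateConstants: K1=%.4g k2=%.4g k3=%.4g [1/min], KH=%.4g [1/h], k4=%.4g k5=%.4g [1/min]\n",
    object@K1, object@k2, object@k3, object@KH, object@k4, object@k5))
})

## ---------------------------------------------------------------------------
## InputFunction
## ---------------------------------------------------------------------------

#' Parametric plasma input function
#'
#' Biexponential plasma concentration curve
#' Cp(t) = A1 exp(-lambda1 (t - delay)) + A2 exp(-lambda2 (t - delay))
#' for t >= delay and 0 before. A negative A2 (with lambda2 > lambda1)
#' gives the usual bolus shape rising from zero; validity requires
#' Cp(t) >= 0 everywhere.
#'
#' @slot A1,A2 amplitudes (SUV).
#' @slot lambda1,lambda2 decay rates (1/min), positive.
#' @slot delay appearance delay (min), >= 0.
#'
#' @export
setClass("InputFunction",
  representation(A1 = "numeric", A2 = "numeric",
                 lambda1 = "numeric", lambda2 = "numeric", delay = "numeric"),
  validity = function(object) {
    p <- c(object@A1, object@A2, object@lambda1, object@lambda2, object@delay)
    if (any(!is.finite(p))) return("parameters must be finite")
    if (object@lambda1 <= 0 || object@lambda2 <= 0)
      return("decay rates must be positive")
    if (object@delay < 0) return("delay must be >= 0")
    tt <- object@delay + seq(0, 120, by = 0.02)
    if (min(.cpEval(object, tt)) < -1e-10)
      return("Cp(t) must be non-negative for all t")
    TRUE
  }
)

.cpEval <- function(input, t) {
  tau <- t - input@delay
  out <- ifelse(tau < 0, 0,
                input@A1 * exp(-input@lambda1 * pmax(tau, 0)) +
                input@A2 * exp(-input@lambda2 * pmax(tau, 0)))
  out
}

#' Construct a plasma input function
#'
#' Defaults give a bolus peaking within the first minute and negligible
#' (< 1 percent of peak) by 15 min, the regime in which late-washout
#' mono-exponential fitting is valid.
#'
#' @param A1,A2 amplitudes (SUV). A2 may be negative to model the rise.
#' @param lambda1,lambda2 decay rates (1/min).
#' @param delay appearance delay (min).
#' @return An [InputFunction-class] object.
#' @export
inputFunction <- function(A1 = 9.5, A2 = -9.5, lambda1 = 0.55,
                          lambda2 = 6.0, delay = 0) {
  new("InputFunction", A1 = as.numeric(A1), A2 = as.numeric(A2),
      lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2),
      delay = as.numeric(delay))
}

#' Evaluate a plasma input function
#'
#' @param input an [InputFunction-class].
#' @param t times (min).
#' @return Cp(t) values (SUV).
#' @export
cpValues <- function(input, t) .cpEval(input, t)

#' Time of maximal plasma concentration
#'
#' Analytic argmax of the biexponential. For two positive amplitudes the
#' curve is decreasing and the peak sits at the delay; for a rising bolus
#' (one negative amplitude) the stationary point is
#' delay + log((A2 lambda2)/(A1 lambda1)) / (lambda2 - lambda1) in terms
#' of the absolute amplitudes.
#'
#' @param input an [InputFunction-class].
#' @return Peak time (min).
#' @export
cpPeakTime <- function(input) {
  a1 <- input@A1 * input@lambda1
  a2 <- -input@A2 * input@lambda2
  if (a2 <= 0 || input@lambda2 == input@lambda1) return(input@delay)
  tstar <- log(a2 / a1) / (input@lambda2 - input@lambda1)
  input@delay + max(0, tstar)
}

#' Late-time extinction ratio of the input function
#'
#' Cp(t)/max(Cp) at a check time, used to verify the "input negligible by
#' 15 min" condition that licenses late-window mono-exponential fitting.
#'
#' @param input an [InputFunction-class].
#' @param at check time (min), default 15.
#' @return Ratio in [0, 1].
#' @export
extinctionRatio <- function(input, at = 15) {
  peak <- .cpEval(input, cpPeakTime(input))
  if (peak <= 0) return(0)
  .cpEval(input, at) / peak
}

setMethod("show", "InputFunction", function(object) {
  cat(sprintf(
    "InputFunction: Cp(t) = %.4g e^(-%.4g t) + %.4g e^(-%.4g t), delay %.3g min\n",
    object@A1, object@lambda1, object@A2, object@lambda2, object@delay))
  cat(sprintf("  peak %.4g SUV at %.3g min; Cp(15)/peak = %.3g\n",
              .cpEval(object, cpPeakTime(object)), cpPeakTime(object),
              extinctionRatio(object)))
})

## ---------------------------------------------------------------------------
## CompartmentCurves
## ---------------------------------------------------------------------------

#' Tissue compartment concentration curves
#'
#' Solution of the compartment model on a time grid: C1 (free probe),
#' C2 (covalent complex), C3 (tissue CO2), all in the units of the driving
#' input (typically SUV).
#'
#' @slot time time grid (min).
#' @slot C1,C2,C3 compartment concentration curves.
#'
#' @export
setClass("CompartmentCurves",
  representation(time = "numeric", C1 = "numeric", C2 = "numeric",
                 C3 = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@C1) != n || length(object@C2) != n ||
        length(object@C3) != n)
      return("curve lengths must match the time grid")
    if (any(!is.finite(c(object@C1, object@C2, object@C3))))
      return("curves must be finite")
    TRUE
  }
)

#' Total tissue activity
#'
#' @param curves a [CompartmentCurves-class].
#' @return C1 + C2 + C3 elementwise.
#' @export
totalActivity <- function(curves) curves@C1 + curves@C2 + curves@C3

setMethod("show", "CompartmentCurves", function(object) {
  tot <- totalActivity(object)
  cat(sprintf("CompartmentCurves: %d time points (%.3g - %.3g min), peak total %.4g\n",
              length(object@time), min(object@time), max(object@time), max(tot)))
})

## ---------------------------------------------------------------------------
## TimeActivityCurve
## ---------------------------------------------------------------------------

#' Frame-resolved time-activity curve
#'
#' One activity value per frame of a [FrameSchedule-class], with a units
#' tag ("SUV", "percentID", "percent_max", ...) and optional per-frame
#' fitting weights.
#'
#' @slot schedule the frame schedule.
#' @slot values one activity value per frame.
#' @slot units character units tag.
#' @slot weights optional per-frame weights (length 0 or nFrames).
#'
#' @export
setClass("TimeActivityCurve",
  representation(schedule = "FrameSchedule", values = "numeric",
                 units = "character", weights = "numeric"),
  validity = function(object) {
    n <- nFrames(object@schedule)
    if (length(object@values) != n)
      return("values length must equal the number of frames")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (length(object@weights) != 0L && length(object@weights) != n)
      return("weights must be empty or one per frame")
    if (length(object@units) != 1L) return("units must be a single string")
    TRUE
  }
)

#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param values one activity value per frame.
#' @param units units tag; default "SUV".
#' @param weights optional per-frame weights.
#' @return A [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(schedule, values, units = "SUV",
                              weights = numeric(0)) {
  new("TimeActivityCurve", schedule = schedule, values = as.numeric(values),
      units = units, weights = as.numeric(weights))
}

#' @describeIn timeActivityCurve Frame activity values.
#' @param tac a [TimeActivityCurve-class].
#' @export
tacValues <- function(tac) tac@values

#' @describeIn timeActivityCurve The curve's frame schedule.
#' @export
tacSchedule <- function(tac) tac@schedule

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve: %d frames, units %s, range %.4g - %.4g\n",
              nFrames(object@schedule), object@units,
              min(object@values), max(object@values)))
})

## ---------------------------------------------------------------------------
## DynamicImage
## ---------------------------------------------------------------------------

#' 4D dynamic PET image
#'
#' Voxel activity over frames: a 4D array (x, y, z, frame) in SUV with its
#' frame schedule and voxel size.
#'
#' @slot data 4D numeric array; 4th axis indexes frames.
#' @slot schedule the frame schedule (length must match the 4th axis).
#' @slot voxelSize voxel edge lengths (mm), length 3.
#'
#' @export
setClass("DynamicImage",
  representation(data = "array", schedule = "FrameSchedule",
                 voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array (x, y, z, frame)")
    if (d[4L] != nFrames(object@schedule))
      return("4th dimension must equal the number of frames")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive lengths (mm)")
    if (any(!is.finite(object@data))) return("voxel values must be finite")
    TRUE
  }
)

#' Construct a dynamic image
#'
#' @param data 4D array (x, y, z, frame).
#' @param schedule a [FrameSchedule-class].
#' @param voxelSize voxel size in mm (length 3), default 0.5 mm isotropic.
#' @return A [DynamicImage-class].
#' @export
dynamicImage <- function(data, schedule, voxelSize = c(0.5, 0.5, 0.5)) {
  new("DynamicImage", data = data, schedule = schedule,
      voxelSize = as.numeric(voxelSize))
}

#' @describeIn dynamicImage The 4D voxel array.
#' @param img a [DynamicImage-class].
#' @export
imageData <- function(img) img@data

#' @describeIn dynamicImage The image frame schedule.
#' @export
imageSchedule <- function(img) img@schedule

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicImage: %d x %d x %d voxels x %d frames, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(object@voxelSize, 3), collapse = " x ")))
})

## ---------------------------------------------------------------------------
## RelativeKHMap
## ---------------------------------------------------------------------------

#' Relative hydrolysis-rate parametric map
#'
#' Voxel-wise relative efflux fraction (early-mean minus late-mean over
#' early-mean), defined only where the early average exceeds a threshold.
#' Values are <= 1 where defined; negative values (net accumulation, as for
#' a non-hydrolyzable probe) are preserved, not clipped.
#'
#' @slot map 3D map; NaN outside the validity mask.
#' @slot mask logical 3D validity mask.
#' @slot threshold early-mean threshold used for the mask (SUV).
#' @slot nMasked number of voxels excluded by the threshold.
#'
#' @export
setClass("RelativeKHMap",
  representation(map = "array", mask = "array", threshold = "numeric",
                 nMasked = "integer"),
  validity = function(object) {
    if (length(dim(object@map)) != 3L) return("map must be 3D")
    if (!identical(dim(object@map), dim(object@mask)))
      return("map and mask dimensions must match")
    if (!is.logical(object@mask)) return("mask must be logical")
    vals <- object@map[object@mask]
    if (any(!is.finite(vals))) return("map must be finite inside the mask")
    if (any(vals > 1 + 1e-12)) return("map values cannot exceed 1")
    TRUE
  }
)

setMethod("show", "RelativeKHMap", function(object) {
  v <- object@map[object@mask]
  cat(sprintf(
    "RelativeKHMap: %s voxels, %d in mask (%d below threshold %.3g SUV)\n",
    paste(dim(object@map), collapse = " x "), sum(object@mask),
    object@nMasked, object@threshold))
  if (length(v))
    cat(sprintf("  in-mask values: mean %.4g, range %.4g - %.4g\n",
                mean(v), min(v), max(v)))
})

## ---------------------------------------------------------------------------
## PHResponseModel / DeactivationRule
## ---------------------------------------------------------------------------

#' pH dose-response model for hydrolysis activity
#'
#' Four-parameter logistic in pH (base 10) linking intracellular pH to the
#' fractional hydrolysis activity of the probe-enzyme complex:
#' f(pH) = floor + (ceiling - floor) / (1 + 10^(hill (ph50 - pH))).
#' The default half-maximal pH is 5.3, the measured half-max of CO2
#' production in brain homogenate.
#'
#' @slot ph50 pH at half-maximal activity.
#' @slot hill slope factor (> 0).
#' @slot floor minimal fractional activity, in [0, 1).
#' @slot ceiling maximal fractional activity, in (floor, 1].
#'
#' @export
setClass("PHResponseModel",
  representation(ph50 = "numeric", hill = "numeric",
                 floor = "numeric", ceiling = "numeric"),
  validity = function(object) {
    if (!is.finite(object@ph50)) return("ph50 must be finite")
    if (object@hill <= 0) return("hill must be positive")
    if (object@floor < 0 || object@ceiling > 1 ||
        object@floor >= object@ceiling)
      return("need 0 <= floor < ceiling <= 1")
    TRUE
  }
)

#' Construct a pH-response model
#'
#' @param ph50 pH of half-maximal hydrolysis activity; default 5.3.
#' @param hill logistic slope factor; default 1.
#' @param floor,ceiling minimal and maximal fractional activity.
#' @return A [PHResponseModel-class].
#' @export
phResponseModel <- function(ph50 = 5.3, hill = 1, floor = 0, ceiling = 1) {
  new("PHResponseModel", ph50 = as.numeric(ph50), hill = as.numeric(hill),
      floor = as.numeric(floor), ceiling = as.numeric(ceiling))
}

setMethod("show", "PHResponseModel", function(object) {
  cat(sprintf(
    "PHResponseModel: ph50 %.3g, hill %.3g, activity range [%.3g, %.3g]\n",
    object@ph50, object@hill, object@floor, object@ceiling))
})

#' Severe-acid binding deactivation rule
#'
#' Below a cutoff pH the probe's binding to the enzyme is additionally
#' suppressed (denaturation regime): the association rate is multiplied by
#' a factor in [0, 1]. Applied to binding (k3 / k_on), not to hydrolysis,
#' because the severe-acid loss is a loss of binding affinity.
#'
#' @slot phCutoff pH below which binding is suppressed; default 4.8.
#' @slot factor multiplier applied to the binding rate, in [0, 1].
#'
#' @export
setClass("DeactivationRule",
  representation(phCutoff = "numeric", factor = "numeric"),
  validity = function(object) {
    if (object@factor < 0 || object@factor > 1)
      return("factor must lie in [0, 1]")
    TRUE
  }
)

#' Construct a deactivation rule
#'
#' @param phCutoff cutoff pH; default 4.8.
#' @param factor binding-rate multiplier below the cutoff; default 0.15.
#' @return A [DeactivationRule-class].
#' @export
deactivationRule <- function(phCutoff = 4.8, factor = 0.15) {
  new("DeactivationRule", phCutoff = as.numeric(phCutoff),
      factor = as.numeric(factor))
}

## ---------------------------------------------------------------------------
## InVitroParams
## ---------------------------------------------------------------------------

#' Parameters of the in vitro CO2-collection assay simulation
#'
#' Closed-system homogenate assay: unbound probe binds the enzyme (kOn),
#' the covalent complex hydrolyzes at a pH-modulated rate, dissolved CO2 is
#' bubbled into a trap (kTrap), and a fixed nonspecific fraction partitions
#' to the pellet at t = 0. All pools in percent of incubated dose (%ID).
#'
#' @slot kOn binding rate (1/min).
#' @slot bMax reactive-enzyme capacity in %ID-equivalents; NA disables the
#'   capacity limit (pure linear kinetics, the default).
#' @slot kHMax maximal hydrolysis rate (1/h) at full activity.
#' @slot ph homogenate pH.
#' @slot phModel a [PHResponseModel-class] scaling kHMax.
#' @slot deactivation a [DeactivationRule-class] scaling kOn at severe pH.
#' @slot kTrap first-order bubbling transfer of dissolved CO2 (1/min).
#' @slot nonspecificFraction fraction of dose partitioned to the pellet.
#' @slot duration incubation time (min).
#' @slot samplingInterval sample spacing (min).
#'
#' @export
setClass("InVitroParams",
  representation(kOn = "numeric", bMax = "numeric", kHMax = "numeric",
                 ph = "numeric", phModel = "PHResponseModel",
                 deactivation = "DeactivationRule", kTrap = "numeric",
                 nonspecificFraction = "numeric", duration = "numeric",
                 samplingInterval = "numeric"),
  validity = function(object) {
    if (object@kOn < 0 || object@kHMax < 0 || object@kTrap < 0)
      return("rates must be >= 0")
    if (!is.na(object@bMax) && object@bMax <= 0)
      return("bMax must be positive when enabled")
    if (object@nonspecificFraction < 0 || object@nonspecificFraction >= 1)
      return("nonspecificFraction must lie in [0, 1)")
    if (object@duration <= 0 || object@samplingInterval <= 0)
      return("duration and samplingInterval must be positive")
    TRUE
  }
)

#' Construct in vitro assay parameters
#'
#' @param kOn binding rate (1/min); default 0.08 (unbound probe nearly
#'   exhausted within the 60-min incubation).
#' @param bMax enzyme capacity (%ID-equivalents); NA (default) = no limit.
#' @param kHMax maximal hydrolysis rate (1/h); default 0.7.
#' @param ph homogenate pH; default 7.4.
#' @param phModel a [PHResponseModel-class]; default [phResponseModel()].
#' @param deactivation a [DeactivationRule-class]; default
#'   [deactivationRule()].
#' @param kTrap bubbling transfer rate (1/min); default 1.
#' @param nonspecificFraction pellet partition at t = 0; default 0.25.
#' @param duration incubation length (min); default 60.
#' @param samplingInterval sample spacing (min); default 5 (bottle-change
#'   interval of the assay).
#' @return An [InVitroParams-class].
#' @export
inVitroParams <- function(kOn = 0.08, bMax = NA_real_, kHMax = 0.7,
                          ph = 7.4, phModel = phResponseModel(),
                          deactivation = deactivationRule(), kTrap = 1,
                          nonspecificFraction = 0.25, duration = 60,
                          samplingInterval = 5) {
  new("InVitroParams", kOn = as.numeric(kOn), bMax = as.numeric(bMax),
      kHMax = as.numeric(kHMax), ph = as.numeric(ph), phModel = phModel,
      deactivation = deactivation, kTrap = as.numeric(kTrap),
      nonspecificFraction = as.numeric(nonspecificFraction),
      duration = as.numeric(duration),
      samplingInterval = as.numeric(samplingInterval))
}

## ---------------------------------------------------------------------------
## MonoExpFit
## ---------------------------------------------------------------------------

#' Mono-exponential washout fit
#'
#' Result of fitting Radioactivity(t) = A exp(-a t) on the late washout
#' window of a TAC; the rate a (1/h) is reported as the hydrolysis rate
#' K_H under the fast-CO2-efflux approximation.
#'
#' @slot amplitude fitted A (TAC units).
#' @slot rate fitted a = K_H (1/h); NA if not converged.
#' @slot window fit window (min), length 2.
#' @slot residualNorm weighted residual 2-norm.
#' @slot converged logical convergence flag.
#' @slot nPoints number of frames used.
#'
#' @export
setClass("MonoExpFit",
  representation(amplitude = "numeric", rate = "numeric",
                 window = "numeric", residualNorm = "numeric",
                 converged = "logical", nPoints = "integer"),
  validity = function(object) {
    if (length(object@window) != 2L || diff(object@window) <= 0)
      return("window must be two increasing times")
    TRUE
  }
)

#' @describeIn fitMonoExp Fitted hydrolysis rate K_H in 1/h (NA if the fit
#'   did not converge).
#' @param fit a [MonoExpFit-class].
#' @export
khValue <- function(fit) fit@rate

setMethod("show", "MonoExpFit", function(object) {
  if (isTRUE(object@converged)) {
    cat(sprintf(
      "MonoExpFit: A = %.4g, K_H = %.4g 1/h (window %g-%g min, %d frames, resid %.3g)\n",
      object@amplitude, object@rate, object@window[1], object@window[2],
      object@nPoints, object@residualNorm))
  } else {
    cat("MonoExpFit: not converged (parameters withheld)\n")
  }
})

## ---------------------------------------------------------------------------
## ScenarioSpec / PhantomSpec
## ---------------------------------------------------------------------------

#' Simulation scenario specification
#'
#' A named study condition binding per-region rate constants, an input
#' function, optional regional pH (routed through the pH-response model),
#' rate-switch events (chase/blocking) and a noise level. The seed fully
#' determines all stochastic output derived from the scenario.
#'
#' @slot name scenario name.
#' @slot regions named list of [RateConstants-class], one per region.
#' @slot regionPH named numeric of regional pH values (may be empty; NA =
#'   use the rates as given).
#' @slot input the [InputFunction-class] driving all regions.
#' @slot events list of rate-switch events, each
#'   \code{list(time =, region =, rates =)}; empty for static rates.
#' @slot noiseLevel fractional frame-noise level (0 = noise free).
#' @slot seed integer seed.
#'
#' @export
setClass("ScenarioSpec",
  representation(name = "character", regions = "list", regionPH = "numeric",
                 input = "InputFunction", events = "list",
                 noiseLevel = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@regions) == 0L) return("at least one region required")
    if (is.null(names(object@regions)) || any(names(object@regions) == ""))
      return("regions must be named")
    ok <- vapply(object@regions, function(r) is(r, "RateConstants"), logical(1))
    if (!all(ok)) return("regions must be RateConstants objects")
    if (object@noiseLevel < 0) return("noiseLevel must be >= 0")
    TRUE
  }
)

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec '%s': %d region(s) [%s], noise %.3g, seed %d\n",
              object@name, length(object@regions),
              paste(names(object@regions), collapse = ", "),
              object@noiseLevel, object@seed))
})

#' Digital phantom specification
#'
#' Grid geometry plus the scenario bound to the phantom's region labels.
#' The phantom is a schematic two-hemisphere ellipsoid (not an anatomical
#' atlas): background 0, brain tissue, and a lesion confined to the
#' ipsilateral hemisphere.
#'
#' @slot gridDim image dimensions (x, y, z).
#' @slot voxelSize voxel size (mm), length 3.
#' @slot scenario a [ScenarioSpec-class] with regions named
#'   "contralateral" and "ipsilateral".
#'
#' @export
setClass("PhantomSpec",
  representation(gridDim = "integer", voxelSize = "numeric",
                 scenario = "ScenarioSpec"),
  validity = function(object) {
    if (length(object@gridDim) != 3L || any(object@gridDim < 8L))
      return("gridDim must be three dimensions >= 8")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive lengths")
    rn <- names(object@scenario@regions)
    if (!all(c("contralateral", "ipsilateral") %in% rn))
      return("scenario must define 'contralateral' and 'ipsilateral' regions")
    TRUE
  }
)

#' Construct a phantom specification
#'
#' @param scenario a [ScenarioSpec-class]; default the 3-4 h occlusion
#'   scenario [scenarioSpec()]("mcao_3_4h").
#' @param gridDim image dimensions; default c(64, 64, 32).
#' @param voxelSize voxel size in mm; default 0.5 isotropic.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(scenario = scenarioSpec("mcao_3_4h"),
                        gridDim = c(64L, 64L, 32L),
                        voxelSize = c(0.5, 0.5, 0.5)) {
  new("PhantomSpec", gridDim = as.integer(gridDim),
      voxelSize = as.numeric(voxelSize), scenario = scenario)
}
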