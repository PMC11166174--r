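## pH dose-response: logistic link between intracellular pH and fractional
## hydrolysis activity of the probe-enzyme complex. Half-max defaults to
## pH 5.3 (measured half-max of CO2 production in brain homogenate); the
## slope is configurable because only the half-max point is constrained by
## measurement.

#' Fractional hydrolysis activity at a given pH
#'
#' Evaluates the logistic dose-response
#' f(pH) = floor + (ceiling - floor) / (1 + 10^(hill (ph50 - pH))),
#' monotone non-decreasing in pH and bounded by [floor, ceiling]. At
#' ph50 the response is exactly (floor + ceiling)/2.
#'
#' @param ph pH value(s).
#' @param model a [PHResponseModel-class]; default [phResponseModel()].
#' @return Fractional activity in [floor, ceiling], same length as ph.
#' @examples
#' hydrolysisFraction(5.3)            # 0.5
#' hydrolysisFraction(c(4, 6, 7.4))
#' @export
hydrolysisFraction <- function(ph, model = phResponseModel()) {
  stopifnot(is(model, "PHResponseModel"))
  validObject(model)
  model@floor + (model@ceiling - model@floor) /
    (1 + 10^(model@hill * (model@ph50 - ph)))
}

#' pH-modulated hydrolysis rate
#'
#' Scales a maximal hydrolysis rate by the fractional activity at the
#' given pH: K_H(pH) = kHMax * hydrolysisFraction(pH, model). This is how
#' intracellular acidification lowers the apparent washout rate.
#'
#' @param kHMax maximal hydrolysis rate (1/h), >= 0.
#' @param ph pH value(s).
#' @param model a [PHResponseModel-class].
#' @return K_H in 1/h, monotone non-decreasing in pH.
#' @examples
#' modulatedKH(0.7, 7.0)
#' @export
modulatedKH <- function(kHMax, ph, model = phResponseModel()) {
  if (!is.finite(kHMax) || kHMax < 0) stop("kHMax must be >= 0")
  kHMax * hydrolysisFraction(ph, model)
}

#' pH of half-maximal hydrolysis activity
#'
#' The pH at which the response equals (floor + ceiling)/2; for the
#' logistic form this is the ph50 parameter itself, returned after
#' validating that the model is non-degenerate.
#'
#' @param model a [PHResponseModel-class].
#' @return The half-maximal pH.
#' @examples
#' phHalfMax(phResponseModel())  # 5.3
#' @export
phHalfMax <- function(model = phResponseModel()) {
  stopifnot(is(model, "PHResponseModel"))
  validObject(model)
  if (model@ceiling - model@floor < 1e-12)
    stop("degenerate model: floor equals ceiling")
  model@ph50
}
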