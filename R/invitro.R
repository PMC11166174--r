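## Closed-system simulation of the homogenate CO2-collection assay:
## unbound probe (C1) binds the enzyme (kOn) to form a covalent complex
## (C2), which hydrolyzes at a pH-modulated rate to dissolved CO2 (C3);
## continuous bubbling transfers dissolved CO2 to an external trap (kTrap).
## A fixed nonspecific fraction partitions to the pellet instantly at t=0.
## Everything is in percent of incubated dose (%ID) and the five pools sum
## to 100 %ID at all times.

.assayRates <- function(params) {
  frac <- hydrolysisFraction(params@ph, params@phModel)
  kh <- params@kHMax / 60 * frac            # 1/min
  kOn <- params@kOn
  if (params@ph < params@deactivation@phCutoff)
    kOn <- kOn * params@deactivation@factor
  list(kOn = kOn, kh = kh)
}

#' Simulate the in vitro CO2-collection assay
#'
#' Integrates the closed homogenate system and returns the sampled pool
#' time series. In the default linear mode (no capacity limit) the system
#' is solved exactly by matrix exponentials; with a finite enzyme capacity
#' \code{bMax} the binding flux becomes kOn C1 (1 - C2/bMax) and a stiff
#' ODE solver is used. Hydrolyzed enzyme is not regenerated.
#'
#' The returned data frame has one row per sample time with columns
#' \code{time, C1, C2, C3, trap, nonspecific, total, c2AUC}; \code{c2AUC}
#' is the running time integral of the complex pool (%ID min), from which
#' the effective CO2 production rate can be recovered as
#' (C3 + trap)/c2AUC.
#'
#' @param params an [InVitroParams-class].
#' @return A data.frame of pool values (%ID) over time.
#' @examples
#' head(simulateAssay(inVitroParams()))
#' @export
simulateAssay <- function(params = inVitroParams()) {
  stopifnot(is(params, "InVitroParams"))
  validObject(params)
  r <- .assayRates(params)
  ns <- 100 * params@nonspecificFraction
  x0 <- c(C1 = 100 - ns, C2 = 0, C3 = 0, trap = 0, I = 0)
  times <- seq(0, params@duration, by = params@samplingInterval)
  if (times[length(times)] < params@duration)
    times <- c(times, params@duration)

  if (is.na(params@bMax)) {
    ## linear: states (C1, C2, C3, trap, integral of C2)
    M <- matrix(0, 5, 5)
    M[1, 1] <- -r$kOn
    M[2, 1] <- r$kOn;  M[2, 2] <- -r$kh
    M[3, 2] <- r$kh;   M[3, 3] <- -params@kTrap
    M[4, 3] <- params@kTrap
    M[5, 2] <- 1
    states <- t(vapply(times, function(tt) .expmStep(M, tt, x0),
                       numeric(5)))
  } else {
    deriv <- function(t, y, p) {
      bind <- r$kOn * y[1] * max(0, 1 - y[2] / params@bMax)
      list(c(-bind,
             bind - r$kh * y[2],
             r$kh * y[2] - params@kTrap * y[3],
             params@kTrap * y[3],
             y[2]))
    }
    sol <- deSolve::lsoda(x0, times, deriv, parms = NULL,
                          rtol = 1e-12, atol = 1e-12)
    states <- unname(sol[, -1, drop = FALSE])
  }
  states[states < 0 & states > -1e-12] <- 0
  data.frame(time = times,
             C1 = states[, 1], C2 = states[, 2], C3 = states[, 3],
             trap = states[, 4], nonspecific = ns,
             total = rowSums(states[, 1:4, drop = FALSE]) + ns,
             c2AUC = states[, 5])
}

#' pH sweep of the in vitro assay
#'
#' Runs the assay at each pH and tabulates the final pool split plus the
#' effective CO2 production rate. The rate is measured from the simulated
#' output as total CO2 produced divided by the complex exposure,
#' (C3 + trap)/AUC(C2), which for first-order hydrolysis equals the
#' pH-modulated rate constant; it is reported in 1/h.
#'
#' @param params an [InVitroParams-class]; its \code{ph} slot is
#'   overridden per sweep entry.
#' @param phValues numeric vector of at least 2 pH values.
#' @param labels optional pass-through labels (e.g. lactic acid mM) of the
#'   same length.
#' @return A data.frame with one row per pH: ph, label (if given), final
#'   C1, C2, C3, trap, nonspecific (%ID), c2AUC and co2Rate (1/h).
#' @examples
#' phSweep(inVitroParams(), c(7.4, 6.5, 5.7, 4.8))
#' @export
phSweep <- function(params = inVitroParams(), phValues,
                    labels = NULL) {
  if (length(phValues) < 2L) stop("need at least 2 pH values")
  if (!is.null(labels) && length(labels) != length(phValues))
    stop("labels must match phValues in length")
  rows <- lapply(phValues, function(p) {
    pp <- params
    pp@ph <- as.numeric(p)
    res <- simulateAssay(pp)
    fin <- res[nrow(res), ]
    co2 <- fin$C3 + fin$trap
    data.frame(ph = as.numeric(p),
               C1 = fin$C1, C2 = fin$C2, C3 = fin$C3, trap = fin$trap,
               nonspecific = fin$nonspecific, c2AUC = fin$c2AUC,
               co2Rate = if (fin$c2AUC > 0) 60 * co2 / fin$c2AUC else 0)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out$label <- labels
  out
}

#' Fit the half-maximal pH from a sweep table
#'
#' Least-squares logistic fit of the normalized CO2 production rate versus
#' pH: rate = ceiling / (1 + 10^(hill (ph50 - pH))), floor fixed at 0.
#' Accepts the output of [phSweep()] (column \code{co2Rate}) or any data
#' frame with columns \code{ph} and \code{rate}; replicate rows at the
#' same pH are allowed.
#'
#' @param sweep a data.frame with columns \code{ph} and \code{co2Rate}
#'   (or \code{rate}).
#' @return A list with elements \code{ph50}, \code{hill}, \code{ceiling}
#'   and the underlying \code{nls} fit.
#' @examples
#' sw <- phSweep(inVitroParams(), seq(4, 7.4, by = 0.4))
#' fitPH50FromSweep(sw)$ph50
#' @export
fitPH50FromSweep <- function(sweep) {
  if (!is.data.frame(sweep) || !"ph" %in% names(sweep))
    stop("sweep must be a data.frame with a 'ph' column")
  ycol <- if ("co2Rate" %in% names(sweep)) "co2Rate" else "rate"
  if (!ycol %in% names(sweep))
    stop("sweep must contain a 'co2Rate' or 'rate' column")
  ph <- sweep$ph
  y <- sweep[[ycol]]
  if (length(unique(ph)) < 4L)
    stop("need at least 4 distinct pH values spanning the transition")
  ymax <- max(y)
  if (ymax <= 0 || (max(y) - min(y)) < 1e-8 * max(abs(y), 1))
    stop("degenerate sweep: response is flat, cannot locate a transition")
  ## start ph50 at the pH whose response is closest to half the maximum
  p0 <- ph[which.min(abs(y - ymax / 2))]
  fit <- minpack.lm::nlsLM(
    y ~ ceiling / (1 + 10^(hill * (ph50 - ph))),
    start = list(ceiling = ymax, ph50 = p0, hill = 1),
    lower = c(ceiling = 0, ph50 = min(ph) - 2, hill = 0.05),
    upper = c(ceiling = Inf, ph50 = max(ph) + 2, hill = 20),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(ph50 = unname(cf["ph50"]), hill = unname(cf["hill"]),
       ceiling = unname(cf["ceiling"]), fit = fit)
}
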