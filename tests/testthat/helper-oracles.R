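# Independent oracles used across the suite.

# Stiff-integrator reference for the compartment model: the ODE right-hand
# side is written directly from the model equations with the plasma curve
# evaluated inside the derivative (no augmentation, no matrix exponential),
# integrated by lsoda at very tight tolerance. Fully independent of the
# package's propagator.
oracleSolve <- function(rates, input, times, initial = c(0, 0, 0),
                        co2Input = NULL) {
  kh <- rates@KH / 60
  cp <- function(t) cpValues(input, t)
  cpCo2 <- if (is.null(co2Input)) function(t) 0 else
    function(t) cpValues(co2Input, t)
  rhs <- function(t, y, p) {
    list(c(rates@K1 * cp(t) - (rates@k2 + rates@k3) * y[1],
           rates@k3 * y[1] - kh * y[2],
           kh * y[2] - rates@k5 * y[3] + rates@k4 * cpCo2(t)))
  }
  sol <- deSolve::lsoda(initial, times, rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  unname(sol[, -1, drop = FALSE])
}

# random valid rate set for property tests
randomRates <- function() {
  rateConstants(K1 = runif(1, 0.05, 0.5), k2 = runif(1, 0.05, 0.8),
                k3 = runif(1, 0.1, 1.2), KH = runif(1, 0.1, 1.5),
                k4 = 0, k5 = runif(1, 0.5, 2.5))
}

randomInput <- function() {
  inputFunction(A1 = runif(1, 1, 10), A2 = runif(1, 0.2, 3),
                lambda1 = runif(1, 0.3, 0.9), lambda2 = runif(1, 0.05, 0.25),
                delay = runif(1, 0, 1))
}

# exact frame-averaged model TAC for a single-region scenario
modelTac <- function(rates, input = inputFunction(),
                     schedule = defaultFrameSchedule()) {
  petkh:::.frameAverageModel(rates, input, schedule)
}
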