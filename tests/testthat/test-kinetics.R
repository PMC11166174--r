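test_that("rate and schedule containers enforce their invariants", {
  expect_error(rateConstants(K1 = -0.1, k2 = 0.3, k3 = 0.6, KH = 0.7),
               "negative")
  r <- rateConstants(K1 = 0.2, k2 = 0.3, k3 = 0.6, KH = 0.72)
  expect_equal(kHPerMin(r) * 60, r@KH)

  expect_error(frameSchedule(c(0, 2), c(1, 3)), "contiguous")
  expect_error(frameSchedule(0, 0), "positive")
  sched <- defaultFrameSchedule()
  expect_equal(nFrames(sched), 26L)
  expect_equal(frameEnds(sched)[26], 90)
  expect_equal(frameDurations(sched), c(rep(1, 4), rep(2, 8), rep(5, 14)))
})

test_that("input function is non-negative, peaks where the closed form says, and is gone by 15 min", {
  inp <- inputFunction()
  tt <- seq(0, 120, by = 0.01)
  expect_true(all(cpValues(inp, tt) >= 0))
  # dense grid-search oracle for the argmax
  tstarGrid <- tt[which.max(cpValues(inp, tt))]
  expect_lt(abs(cpPeakTime(inp) - tstarGrid), 0.01)  # grid resolution
  expect_lt(extinctionRatio(inp), 0.01)
  # a decreasing biexponential peaks at its delay
  dec <- inputFunction(A1 = 5, A2 = 2, lambda1 = 0.5, lambda2 = 0.1,
                       delay = 0.7)
  expect_equal(cpPeakTime(dec), 0.7)
  expect_error(inputFunction(A1 = 1, A2 = -5, lambda1 = 0.5, lambda2 = 6),
               "non-negative")
})

test_that("null system stays identically zero and bad inputs are rejected", {
  r0 <- rateConstants(0, 0, 0, 0, 0, 0)
  zin <- inputFunction(A1 = 0, A2 = 0)
  cc <- solveCompartments(r0, zin, seq(0, 90, by = 5))
  expect_equal(totalActivity(cc), rep(0, length(cc@time)))
  expect_error(solveCompartments(r0, zin, c(0, 5, 3)), "increasing")
  expect_error(solveCompartments(r0, zin, c(1, 5)), "start at 0")
})

test_that("with no input and fast CO2 efflux, total activity decays as exp(-KH t)", {
  # C2(0) = 1, k5 = 100 KH: C1 = 0, C3 is quasi-steady and <= KH/k5 of C2,
  # so total tracks the complex pool decaying at KH
  kh <- 0.62
  r <- rateConstants(K1 = 0, k2 = 0.3, k3 = 0.6, KH = kh,
                     k5 = 100 * kh / 60)
  cc <- solveCompartments(r, inputFunction(A1 = 0, A2 = 0),
                          seq(0, 90, by = 1), initial = c(0, 1, 0))
  sel <- cc@time >= 15
  analytic <- exp(-kh * cc@time[sel] / 60)
  # quasi-steady CO2 adds at most KH/(k5 - KH) = 1/99 to the complex pool
  expect_true(all(abs(totalActivity(cc)[sel] / analytic - 1) <= 1 / 99 + 1e-4))
  expect_true(all(cc@C3[sel] <= (1 / 99) * cc@C2[sel] * (1 + 1e-9)))
  # the washout *rate* matches KH to well under 1%
  slope <- coef(lm(log(totalActivity(cc)[sel]) ~ I(cc@time[sel] / 60)))[2]
  expect_lt(abs(-slope / kh - 1), 0.01)
})

test_that("matrix-exponential solver matches the stiff-integrator oracle", {
  set.seed(42)
  times <- seq(0, 90, by = 1.5)
  worst <- 0
  for (i in 1:20) {
    r <- randomRates()
    inp <- randomInput()
    cc <- solveCompartments(r, inp, times)
    ref <- oracleSolve(r, inp, times, co2Input = NULL)
    got <- cbind(cc@C1, cc@C2, cc@C3)
    relErr <- max(abs(got - ref)) / max(abs(ref))
    worst <- max(worst, relErr)
  }
  expect_lt(worst, 1e-6)
})

test_that("CO2 reuptake pathway (k4 with a plasma CO2 curve) matches the oracle", {
  set.seed(7)
  times <- seq(0, 90, by = 2)
  r <- rateConstants(K1 = 0.2, k2 = 0.3, k3 = 0.6, KH = 0.7,
                     k4 = 0.05, k5 = 1.74)
  inp <- inputFunction()
  co2 <- inputFunction(A1 = 0.8, A2 = 0.4, lambda1 = 0.2, lambda2 = 0.05,
                       delay = 2)
  cc <- solveCompartments(r, inp, times, co2Input = co2)
  ref <- oracleSolve(r, inp, times, co2Input = co2)
  expect_lt(max(abs(cbind(cc@C1, cc@C2, cc@C3) - ref)) / max(ref), 1e-6)
  # pathway inert when no CO2 curve is supplied
  cc0 <- solveCompartments(r, inp, times)
  ccK4off <- solveCompartments(rateConstants(0.2, 0.3, 0.6, 0.7, 0, 1.74),
                               inp, times)
  expect_equal(totalActivity(cc0), totalActivity(ccK4off))
})

test_that("tissue activity is non-increasing once the input is extinguished", {
  set.seed(11)
  for (i in 1:5) {
    r <- randomRates()
    cc <- solveCompartments(r, inputFunction(), seq(0, 90, by = 0.5))
    tot <- totalActivity(cc)
    late <- cc@time >= 20
    expect_true(all(diff(tot[late]) <= 1e-10))
  }
})

test_that("log total activity is linear with slope -KH when k5/KH is large", {
  kh <- 0.7                       # 1/h; k5/KH = 150 on a per-min basis
  r <- rateConstants(K1 = 0.18, k2 = 0.3, k3 = 0.6, KH = kh,
                     k5 = 150 * kh / 60)
  cc <- solveCompartments(r, inputFunction(), seq(0, 90, by = 0.5))
  sel <- cc@time >= 15
  slope <- coef(lm(log(totalActivity(cc)[sel]) ~ I(cc@time[sel] / 60)))[2]
  expect_lt(abs(-slope / kh - 1), 0.02)
})

test_that("pre-blockade lowers the peak and washes out almost completely", {
  inp <- inputFunction()
  times <- seq(0, 90, by = 0.5)
  full <- solveCompartments(rateConstants(0.18, 0.3, 0.6, 0.66), inp, times)
  blocked <- solveCompartments(rateConstants(0.18, 0.3, 0.03, 0.66), inp,
                               times)
  expect_lt(max(totalActivity(blocked)), max(totalActivity(full)))
  # near-complete washout: < 10% of its own peak left at 90 min
  totB <- totalActivity(blocked)
  expect_lt(totB[length(totB)] / max(totB), 0.10)
})

test_that("a chase at 20 min barely changes the curve once the probe is trapped", {
  r <- rateConstants(0.18, 0.3, 0.6, 0.66)
  inp <- inputFunction()
  times <- seq(0, 90, by = 0.5)
  base <- solveCompartments(r, inp, times)
  chased <- solveCompartments(r, inp, times, events = list(list(
    time = 20, rates = rateConstants(0.18, 0.3, 0, 0.66))))
  i20 <- which(times == 20)
  expect_lt(base@C1[i20] / totalActivity(base)[i20], 0.05)
  sel <- times >= 20
  relDiff <- abs(totalActivity(chased)[sel] - totalActivity(base)[sel]) /
    totalActivity(base)[sel]
  expect_lt(max(relDiff), 0.05)
})

test_that("frame averaging matches constants, ramps and an adaptive-quadrature oracle", {
  sched <- defaultFrameSchedule()
  expect_equal(tacValues(frameAverage(function(t) rep(2, length(t)), sched)),
               rep(2, 26))
  # linear integrand: frame mean is the midpoint value, exactly
  expect_equal(tacValues(frameAverage(function(t) t, sched)),
               frameMidpoints(sched))
  f <- function(t) exp(-0.05 * t)
  got <- tacValues(frameAverage(f, sched))
  ref <- mapply(function(a, b) integrate(f, a, b, rel.tol = 1e-12)$value /
                  (b - a),
                frameStarts(sched), frameEnds(sched))
  expect_lt(max(abs(got - ref)), 1e-8)
  expect_error(frameAverage(f, "not a schedule"))
})

test_that("frame averaging a solved curve agrees with averaging the exact solution", {
  r <- rateConstants(0.18, 0.3, 0.6, 0.66)
  cc <- solveCompartments(r, inputFunction(), seq(0, 90, by = 0.1))
  viaSpline <- tacValues(frameAverage(cc, defaultFrameSchedule()))
  exact <- tacValues(modelTac(r))
  # spline interpolation is only approximate around the bolus arrival kink
  expect_lt(max(abs(viaSpline - exact) / max(exact)), 5e-4)
})

test_that("SUV is concentration over dose per weight", {
  expect_equal(toSUV(5 / 300, 5, 300), 1.0)
  expect_equal(toSUV(0, 5, 300), 0.0)
  expect_equal(toSUV(2 * 5 / 300, 5, 300), 2.0)
  expect_error(toSUV(1, 0, 300), "positive")
  expect_error(toSUV(1, 5, -1), "positive")
})

test_that("decay correction doubles one half-life of decay and round-trips", {
  sched <- defaultFrameSchedule()
  true <- rep(3, 26)
  measured <- true * 2^(-frameMidpoints(sched) / 20.4)
  tac <- timeActivityCurve(sched, measured)
  corrected <- decayCorrect(tac, halfLife = 20.4, referenceTime = 0)
  expect_equal(tacValues(corrected), true, tolerance = 1e-12)
  # frame whose midpoint sits one half-life out: corrected = 2x measured
  i <- which.min(abs(frameMidpoints(sched) - 20.4))
  expect_equal(tacValues(corrected)[i] /
                 tacValues(tac)[i], 2, tolerance = 0.1)
  # reference at a frame midpoint leaves that frame unchanged
  ref <- frameMidpoints(sched)[10]
  expect_equal(tacValues(decayCorrect(tac, referenceTime = ref))[10],
               tacValues(tac)[10])
  # round trip
  back <- decayCorrect(corrected, halfLife = 20.4, invert = TRUE)
  expect_equal(tacValues(back), measured, tolerance = 1e-12)
})
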