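makeImage <- function(tacMatrix, dims) {
  # tacMatrix: nvox x nframes
  dynamicImage(array(tacMatrix, dim = c(dims, ncol(tacMatrix))),
               defaultFrameSchedule())
}

test_that("a frame-constant image maps to zero everywhere in mask", {
  img <- makeImage(matrix(1.5, 8 * 8 * 4, 26), c(8, 8, 4))
  khm <- relativeKHMap(img)
  expect_true(all(khm@mask))
  expect_equal(as.numeric(khm@map), rep(0, 8 * 8 * 4))
  expect_equal(khm@nMasked, 0L)
})

test_that("map value equals the frame-mean arithmetic oracle per voxel", {
  sched <- defaultFrameSchedule()
  # frame means of a 0.62 1/h exponential from adaptive quadrature
  fm <- mapply(function(a, b)
    integrate(function(t) exp(-0.62 * t / 60), a, b, rel.tol = 1e-13)$value /
      (b - a), frameStarts(sched), frameEnds(sched))
  img <- makeImage(matrix(fm, 1, 26), c(1, 1, 1))
  khm <- relativeKHMap(img)
  oracle <- (mean(fm[3:10]) - mean(fm[11:26])) / mean(fm[3:10])
  expect_lt(abs(khm@map[1, 1, 1] - oracle), 1e-10)
})

test_that("regions with lower hydrolysis rank below regions with higher", {
  slow <- tacValues(modelTac(rateConstants(0.175, 0.3, 0.6, 0.41)))
  fast <- tacValues(modelTac(rateConstants(0.175, 0.3, 0.6, 0.62)))
  mat <- rbind(matrix(slow, 32, 26, byrow = TRUE),
               matrix(fast, 32, 26, byrow = TRUE))
  img <- makeImage(mat, c(8, 8, 1))
  khm <- relativeKHMap(img)
  labels <- array(rep(1:2, each = 32), dim = c(8, 8, 1))
  summ <- mapRegionSummary(khm, labels)
  expect_lt(summ$mean[summ$region == "region1"],
            summ$mean[summ$region == "region2"])
})

test_that("the map rises monotonically with the underlying hydrolysis rate", {
  khGrid <- seq(0.1, 2, length.out = 12)
  vals <- vapply(khGrid, function(kh) {
    fm <- tacValues(frameAverage(function(t) exp(-kh * t / 60),
                                 defaultFrameSchedule()))
    (mean(fm[3:10]) - mean(fm[11:26])) / mean(fm[3:10])
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # noise-free mono-exponential: map = 1 - late/early exactly
  fm <- tacValues(frameAverage(function(t) exp(-0.5 * t / 60),
                               defaultFrameSchedule()))
  img <- makeImage(matrix(fm, 1, 26), c(1, 1, 1))
  expect_equal(relativeKHMap(img)@map[1, 1, 1],
               1 - mean(fm[11:26]) / mean(fm[3:10]))
})

test_that("the map is invariant to global intensity scaling", {
  tac <- tacValues(modelTac(rateConstants(0.175, 0.3, 0.6, 0.66)))
  img <- makeImage(matrix(tac, 4 * 4 * 2, 26, byrow = TRUE), c(4, 4, 2))
  m1 <- relativeKHMap(img)
  img10 <- dynamicImage(img@data * 10, imageSchedule(img))
  m10 <- relativeKHMap(img10)
  expect_equal(m1@map, m10@map, tolerance = 1e-12)
})

test_that("low-delivery voxels are masked out and counted", {
  tac <- tacValues(modelTac(rateConstants(0.175, 0.3, 0.6, 0.66)))
  mat <- rbind(matrix(tac, 10, 26, byrow = TRUE),
               matrix(0.01, 6, 26))   # early mean 0.01 < 0.2
  img <- makeImage(mat, c(4, 4, 1))
  khm <- relativeKHMap(img, maskThreshold = 0.2)
  expect_equal(khm@nMasked, 6L)
  expect_equal(sum(khm@mask), 10L)
  expect_true(all(is.nan(khm@map[!khm@mask])))
  expect_error(relativeKHMap(img, earlyFrames = 0:5), "out of range")
})

test_that("ROI extraction reproduces single-voxel and uniform cases exactly", {
  tac <- tacValues(modelTac(rateConstants(0.15, 0.3, 0.6, 0.7)))
  mat <- matrix(rnorm(4 * 4 * 2 * 26, 1, 0.1), 32, 26)
  mat[5, ] <- tac
  img <- makeImage(mat, c(4, 4, 2))
  one <- array(FALSE, c(4, 4, 2)); one[5] <- TRUE
  expect_equal(tacValues(extractRoiTac(img, one)), tac)

  uni <- makeImage(matrix(0.8, 32, 26), c(4, 4, 2))
  all <- array(TRUE, c(4, 4, 2))
  expect_equal(tacValues(extractRoiTac(uni, all)), rep(0.8, 26))
  expect_error(extractRoiTac(img, array(FALSE, c(4, 4, 2))), "empty")
  expect_error(extractRoiTac(img, array(TRUE, c(3, 3, 2))), "grid")
})

test_that("region summaries are order-invariant and flag empty regions", {
  img <- makeImage(matrix(1.5, 64, 26), c(4, 4, 4))
  khm <- relativeKHMap(img)
  a <- array(FALSE, c(4, 4, 4)); a[1:10] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[20:40] <- TRUE
  s1 <- mapRegionSummary(khm, list(A = a, B = b))
  s2 <- mapRegionSummary(khm, list(B = b, A = a))
  expect_equal(unlist(s1[s1$region == "A", -1], use.names = FALSE),
               unlist(s2[s2$region == "A", -1], use.names = FALSE))
  expect_equal(s1$mean, c(0, 0))
  expect_equal(s1$sd, c(0, 0))

  # region entirely below threshold is flagged
  low <- makeImage(matrix(0.01, 64, 26), c(4, 4, 4))
  khmLow <- relativeKHMap(low)
  sLow <- mapRegionSummary(khmLow, list(A = a))
  expect_true(sLow$flagged)
})

test_that("ipsilateral map mean falls below contralateral in noisy phantoms", {
  hits <- vapply(1:100, function(s) {
    ph <- generatePhantom(phantomSpec(
      scenario = scenarioSpec("mcao_3_4h", noiseLevel = 0.05, seed = s),
      gridDim = c(16, 16, 8)))
    khm <- relativeKHMap(ph$image)
    summ <- mapRegionSummary(khm, ph$masks[c("ipsilateral", "contralateral")])
    summ$mean[summ$region == "ipsilateral"] <
      summ$mean[summ$region == "contralateral"]
  }, logical(1))
  expect_gte(sum(hits), 95)
})
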