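test_that("TAC CSV round-trips exactly and names missing columns", {
  tac <- modelTac(rateConstants(0.175, 0.3, 0.6, 0.66))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTacCsv(tac, f)
  back <- readTacCsv(f)
  expect_equal(tacValues(back), tacValues(tac), tolerance = 1e-12)
  expect_equal(frameStarts(tacSchedule(back)), frameStarts(tacSchedule(tac)))
  expect_equal(back@units, tac@units)

  df <- read.csv(f)
  df$value <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  expect_error(readTacCsv(f2), "value")
  expect_error(readTacCsv("/nonexistent/tac.csv"), "not found")
})

test_that("dynamic NIfTI + sidecar round-trips and catches frame mismatches", {
  ph <- generatePhantom(phantomSpec(gridDim = c(8, 8, 8)))
  img <- ph$image
  f <- withr::local_tempfile(fileext = ".nii.gz")
  sc <- sub("\\.nii\\.gz$", ".json", f)
  writeDynamicNifti(img, f, sc)
  back <- readDynamicNifti(f, sc)
  expect_equal(imageData(back), unname(imageData(img)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(frameEnds(imageSchedule(back)), frameEnds(imageSchedule(img)))
  expect_equal(back@voxelSize, img@voxelSize)

  shortSched <- frameSchedule(frameStarts(imageSchedule(img))[1:25],
                              frameEnds(imageSchedule(img))[1:25])
  sc2 <- withr::local_tempfile(fileext = ".json")
  writeFrameSidecar(shortSched, sc2)
  expect_error(readDynamicNifti(f, sc2), "25 frames .* 26|sidecar has")
})

test_that("frame sidecars read from both JSON and CSV", {
  sched <- defaultFrameSchedule()
  fj <- withr::local_tempfile(fileext = ".json")
  writeFrameSidecar(sched, fj)
  expect_equal(frameEnds(readFrameSidecar(fj)), frameEnds(sched))
  fc <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t_start_min = frameStarts(sched),
                       t_end_min = frameEnds(sched)), fc, row.names = FALSE)
  expect_equal(frameEnds(readFrameSidecar(fc)), frameEnds(sched))
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(wrong = 1), bad)
  expect_error(readFrameSidecar(bad), "frame_start_min")
})

test_that("scenario YAML configs round-trip losslessly", {
  spec <- scenarioSpec("mcao_3_4h", noiseLevel = 0.05, seed = 42L)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeScenarioConfig(spec, f)
  back <- readScenarioConfig(f)
  expect_equal(back@name, spec@name)
  expect_equal(back@seed, spec@seed)
  expect_equal(back@noiseLevel, spec@noiseLevel)
  for (nm in names(spec@regions)) {
    expect_equal(back@regions[[nm]]@KH, spec@regions[[nm]]@KH)
    expect_equal(back@regions[[nm]]@K1, spec@regions[[nm]]@K1)
  }
  expect_equal(back@input@A1, spec@input@A1)
})

test_that("simulate-fit-report completes end to end near the generator truth", {
  dir <- withr::local_tempdir()
  man <- runPipeline(list(subcommand = "report", scenario = "mcao_3_4h",
                          seed = 5L, outDir = dir))
  rep <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$kh_per_h$contralateral, 0.62, tolerance = 0.05)
  expect_equal(rep$kh_per_h$ipsilateral, 0.41, tolerance = 0.05)
  expect_equal(rep$ips_cont_ratio, 0.41 / 0.62, tolerance = 0.05)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("identical config and seed give identical manifests and artifacts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- list(subcommand = "simulate-tac", scenario = "healthy",
              noise = 0.05, seed = 9L)
  runPipeline(c(cfg, list(outDir = d1)))
  runPipeline(c(cfg, list(outDir = d2)))
  m1 <- readLines(file.path(d1, "manifest.json"))
  m2 <- readLines(file.path(d2, "manifest.json"))
  expect_identical(m1, m2)
  expect_identical(readLines(file.path(d1, "tac_cortex.csv")),
                   readLines(file.path(d2, "tac_cortex.csv")))
})

test_that("pipeline validation errors are informative", {
  dir <- withr::local_tempdir()
  expect_error(runPipeline(list(outDir = dir)), "subcommand")
  expect_error(runPipeline(list(subcommand = "report")), "outDir")
  expect_error(runPipeline(list(subcommand = "no-such", outDir = dir)),
               "unknown subcommand")
  expect_error(runPipeline(list(subcommand = "fit-kh", outDir = dir)),
               "tacPath")
  expect_error(runPipeline(list(subcommand = "fit-kh",
                                tacPath = "/missing.csv", outDir = dir)),
               "not found")
})

test_that("fit-kh and map-kh subcommands produce usable artifacts", {
  dir <- withr::local_tempdir()
  tac <- modelTac(rateConstants(0.175, 0.3, 0.6, 0.62))
  tacPath <- file.path(dir, "tac.csv")
  writeTacCsv(tac, tacPath)
  runPipeline(list(subcommand = "fit-kh", tacPath = tacPath, outDir = dir))
  fit <- jsonlite::read_json(file.path(dir, "fit.json"),
                             simplifyVector = TRUE)
  expect_equal(fit$KH_per_h, 0.62, tolerance = 0.05)
  expect_true(fit$converged)

  ph <- generatePhantom(phantomSpec(gridDim = c(8, 8, 8)))
  imgPath <- file.path(dir, "dyn.nii.gz")
  scPath <- file.path(dir, "dyn.json")
  writeDynamicNifti(ph$image, imgPath, scPath)
  runPipeline(list(subcommand = "map-kh", imagePath = imgPath,
                   sidecarPath = scPath, outDir = dir))
  expect_true(file.exists(file.path(dir, "khmap.nii.gz")))
  summ <- jsonlite::read_json(file.path(dir, "map_summary.json"),
                              simplifyVector = TRUE)
  expect_gt(summ$n_in_mask, 0)
})
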