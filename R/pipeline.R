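## Pipeline driver: a single entry point dispatching the analysis
## subcommands over the package's functions, emitting a JSON manifest
## sufficient to reproduce every artifact (no timestamps, so identical
## configs give identical manifests).

.manifest <- function(config, outputs) {
  list(package = "petkh",
       version = as.character(utils::packageVersion("petkh")),
       subcommand = config$subcommand,
       seed = if (is.null(config$seed)) NA else config$seed,
       parameters = config[setdiff(names(config),
                                   c("subcommand", "outDir"))],
       outputs = outputs)
}

#' Run a pipeline subcommand
#'
#' Dispatches one of the analysis subcommands with a config list and
#' writes its artifacts plus a \code{manifest.json} under
#' \code{config$outDir}. Identical config + seed produce identical
#' artifacts and manifests.
#'
#' \describe{
#'   \item{simulate-tac}{fields: scenario, noise, seed, outDir. Writes one
#'     TAC CSV per region plus \code{truth.json}.}
#'   \item{simulate-phantom}{fields: scenario (or configPath to a YAML),
#'     gridDim, seed, outDir. Writes the 4D NIfTI + sidecar, label mask
#'     and ground-truth maps.}
#'   \item{invitro-sim}{fields: phValues, seed, outDir. Writes
#'     \code{sweep.csv} and the fitted half-max pH.}
#'   \item{fit-kh}{fields: tacPath, window, outDir. Writes
#'     \code{fit.json} with A, K_H (1/h), window, residual norm and the
#'     convergence flag.}
#'   \item{map-kh}{fields: imagePath, sidecarPath, threshold, outDir.
#'     Writes the relative-K_H map NIfTI and a JSON summary.}
#'   \item{report}{fields: scenario, noise, seed, outDir. Simulates,
#'     fits every region and reports K_H per region plus the
#'     ipsilateral/contralateral ratio when both regions exist.}
#' }
#'
#' @param config a named list; must contain \code{subcommand} and
#'   \code{outDir}.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.null(config$subcommand)) stop("config$subcommand is required")
  if (is.null(config$outDir)) stop("config$outDir is required")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(config$subcommand,
    "simulate-tac" = .cmdSimulateTac(config),
    "simulate-phantom" = .cmdSimulatePhantom(config),
    "invitro-sim" = .cmdInvitro(config),
    "fit-kh" = .cmdFitKh(config),
    "map-kh" = .cmdMapKh(config),
    "report" = .cmdReport(config),
    stop(sprintf("unknown subcommand '%s'", config$subcommand)))
  man <- .manifest(config, out)
  jsonlite::write_json(man, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(man)
}

.cfgScenario <- function(config) {
  if (!is.null(config$configPath)) {
    spec <- readScenarioConfig(config$configPath)
  } else {
    spec <- scenarioSpec(
      if (is.null(config$scenario)) "healthy" else config$scenario,
      noiseLevel = if (is.null(config$noise)) 0 else config$noise,
      seed = if (is.null(config$seed)) 1L else as.integer(config$seed))
  }
  spec
}

.cmdSimulateTac <- function(config) {
  spec <- .cfgScenario(config)
  sim <- generateRegionalTacs(spec)
  files <- vapply(names(sim$tacs), function(nm) {
    f <- file.path(config$outDir, paste0("tac_", nm, ".csv"))
    writeTacCsv(sim$tacs[[nm]], f)
    basename(f)
  }, character(1))
  jsonlite::write_json(sim$truth, file.path(config$outDir, "truth.json"),
                       digits = NA, pretty = TRUE)
  list(tacs = unname(files), truth = "truth.json")
}

.cmdSimulatePhantom <- function(config) {
  spec <- .cfgScenario(config)
  gd <- if (is.null(config$gridDim)) c(64L, 64L, 32L)
        else as.integer(config$gridDim)
  ph <- generatePhantom(phantomSpec(scenario = spec, gridDim = gd))
  writeDynamicNifti(ph$image, file.path(config$outDir, "phantom.nii.gz"))
  writeVolumeNifti(ph$labels, file.path(config$outDir, "labels.nii.gz"),
                   ph$image@voxelSize)
  writeVolumeNifti(ph$truth$khMap, file.path(config$outDir, "true_kh.nii.gz"),
                   ph$image@voxelSize)
  writeVolumeNifti(ph$truth$deliveryMap,
                   file.path(config$outDir, "true_delivery.nii.gz"),
                   ph$image@voxelSize)
  list(image = "phantom.nii.gz", sidecar = "phantom.json",
       labels = "labels.nii.gz",
       truth = c("true_kh.nii.gz", "true_delivery.nii.gz"))
}

.cmdInvitro <- function(config) {
  phv <- if (is.null(config$phValues)) c(7.4, 6.9, 6.5, 6.1, 5.7, 5.3, 4.8, 4.2)
         else as.numeric(config$phValues)
  sw <- phSweep(inVitroParams(), phv)
  utils::write.csv(sw, file.path(config$outDir, "sweep.csv"),
                   row.names = FALSE)
  fit <- tryCatch(fitPH50FromSweep(sw), error = function(e) NULL)
  res <- list(ph50 = if (is.null(fit)) NA else fit$ph50,
              hill = if (is.null(fit)) NA else fit$hill)
  jsonlite::write_json(res, file.path(config$outDir, "ph50.json"),
                       auto_unbox = TRUE, digits = NA)
  list(sweep = "sweep.csv", ph50 = "ph50.json")
}

.cmdFitKh <- function(config) {
  if (is.null(config$tacPath)) stop("config$tacPath is required for fit-kh")
  tac <- readTacCsv(config$tacPath)
  window <- if (is.null(config$window)) c(15, 90) else as.numeric(config$window)
  fit <- fitMonoExp(tac, window = window)
  res <- list(A = fit@amplitude, KH_per_h = fit@rate,
              window_min = fit@window, residual_norm = fit@residualNorm,
              converged = fit@converged, n_frames = fit@nPoints)
  jsonlite::write_json(res, file.path(config$outDir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(fit = "fit.json")
}

.cmdMapKh <- function(config) {
  if (is.null(config$imagePath) || is.null(config$sidecarPath))
    stop("config$imagePath and config$sidecarPath are required for map-kh")
  img <- readDynamicNifti(config$imagePath, config$sidecarPath)
  thr <- if (is.null(config$threshold)) 0.2 else as.numeric(config$threshold)
  khm <- relativeKHMap(img, maskThreshold = thr)
  writeVolumeNifti(khm@map, file.path(config$outDir, "khmap.nii.gz"),
                   img@voxelSize)
  v <- khm@map[khm@mask]
  jsonlite::write_json(
    list(n_in_mask = sum(khm@mask), n_masked_out = khm@nMasked,
         threshold = thr, mean = mean(v), sd = stats::sd(v)),
    file.path(config$outDir, "map_summary.json"),
    auto_unbox = TRUE, digits = NA)
  list(map = "khmap.nii.gz", summary = "map_summary.json")
}

.cmdReport <- function(config) {
  spec <- .cfgScenario(config)
  sim <- generateRegionalTacs(spec)
  fits <- lapply(sim$tacs, fitMonoExp)
  kh <- vapply(fits, khValue, numeric(1))
  res <- list(scenario = spec@name, seed = spec@seed,
              noise = spec@noiseLevel,
              kh_per_h = as.list(kh),
              true_kh_per_h = as.list(stats::setNames(sim$truth$KH,
                                                      sim$truth$region)))
  if (all(c("ipsilateral", "contralateral") %in% names(kh))) {
    res$ips_cont_ratio <- ipsContRatio(kh[["ipsilateral"]],
                                       kh[["contralateral"]])
    res$percent_reduction <- percentReduction(kh[["ipsilateral"]],
                                              kh[["contralateral"]])
  }
  jsonlite::write_json(res, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = "report.json")
}
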