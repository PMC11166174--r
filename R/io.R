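## File dialects:
##  - TAC CSV: columns frame_index, t_start_min, t_end_min, value, units
##    (header required, UTF-8).
##  - 4D volumes: NIfTI-1 (.nii/.nii.gz) with a sidecar (JSON or CSV)
##    carrying the frame schedule, since NIfTI-1 has no per-frame timing.
##  - Masks: integer-labelled NIfTI on the image grid.

.TAC_COLUMNS <- c("frame_index", "t_start_min", "t_end_min", "value", "units")

#' Read a TAC from CSV
#'
#' Expects columns \code{frame_index, t_start_min, t_end_min, value,
#' units}; a missing column raises a validation error naming it.
#'
#' @param path CSV file path.
#' @return A [TimeActivityCurve-class].
#' @export
readTacCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TAC_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("TAC CSV is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  df <- df[order(df$frame_index), ]
  timeActivityCurve(frameSchedule(df$t_start_min, df$t_end_min),
                    df$value, units = as.character(df$units[1L]))
}

#' Write a TAC to CSV
#'
#' @param tac a [TimeActivityCurve-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTacCsv <- function(tac, path) {
  stopifnot(is(tac, "TimeActivityCurve"))
  df <- data.frame(frame_index = seq_len(nFrames(tac@schedule)),
                   t_start_min = frameStarts(tac@schedule),
                   t_end_min = frameEnds(tac@schedule),
                   value = tac@values, units = tac@units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a frame-schedule sidecar
#'
#' JSON sidecars hold \code{frame_start_min} and \code{frame_end_min}
#' arrays; CSV sidecars hold columns \code{t_start_min, t_end_min}.
#'
#' @param path sidecar path (.json or .csv).
#' @return A [FrameSchedule-class].
#' @export
readFrameSidecar <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(js$frame_start_min) || is.null(js$frame_end_min))
      stop("sidecar JSON must contain frame_start_min and frame_end_min")
    frameSchedule(js$frame_start_min, js$frame_end_min)
  } else {
    df <- utils::read.csv(path)
    if (!all(c("t_start_min", "t_end_min") %in% names(df)))
      stop("sidecar CSV must contain t_start_min and t_end_min")
    frameSchedule(df$t_start_min, df$t_end_min)
  }
}

#' Write a frame-schedule sidecar (JSON)
#'
#' @param schedule a [FrameSchedule-class].
#' @param path output .json path.
#' @return The path, invisibly.
#' @export
writeFrameSidecar <- function(schedule, path) {
  jsonlite::write_json(list(frame_start_min = frameStarts(schedule),
                            frame_end_min = frameEnds(schedule)),
                       path, digits = NA)
  invisible(path)
}

#' Read a 4D dynamic NIfTI volume with its frame sidecar
#'
#' @param path NIfTI path (.nii or .nii.gz).
#' @param sidecar frame-schedule sidecar path (see [readFrameSidecar()]).
#' @return A [DynamicImage-class].
#' @export
readDynamicNifti <- function(path, sidecar) {
  vol <- RNifti::readNifti(path)
  schedule <- readFrameSidecar(sidecar)
  arr <- array(as.numeric(vol), dim = dim(vol))
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI volume")
  if (dim(arr)[4L] != nFrames(schedule))
    stop(sprintf("sidecar has %d frames but image has %d",
                 nFrames(schedule), dim(arr)[4L]))
  vx <- RNifti::pixdim(vol)
  if (is.null(vx) || length(vx) < 3L) vx <- c(0.5, 0.5, 0.5)
  dynamicImage(arr, schedule, voxelSize = abs(vx[1:3]))
}

#' Write a 4D dynamic NIfTI volume with its frame sidecar
#'
#' @param img a [DynamicImage-class].
#' @param path output NIfTI path.
#' @param sidecar output sidecar (.json) path; default the image path
#'   with a .json extension.
#' @return The image path, invisibly.
#' @export
writeDynamicNifti <- function(img, path,
                              sidecar = sub("\\.nii(\\.gz)?$", ".json", path)) {
  stopifnot(is(img, "DynamicImage"))
  nif <- RNifti::asNifti(img@data)
  RNifti::pixdim(nif) <- c(img@voxelSize, 1)
  RNifti::writeNifti(nif, path)
  writeFrameSidecar(img@schedule, sidecar)
  invisible(path)
}

#' Read / write a 3D mask or map volume
#'
#' @param path NIfTI path.
#' @return \code{readVolumeNifti}: a 3D array.
#' @export
readVolumeNifti <- function(path) {
  vol <- RNifti::readNifti(path)
  array(as.numeric(vol), dim = dim(vol))
}

#' @rdname readVolumeNifti
#' @param vol 3D array to write.
#' @param voxelSize voxel size (mm), default 0.5 isotropic.
#' @export
writeVolumeNifti <- function(vol, path, voxelSize = c(0.5, 0.5, 0.5)) {
  nif <- RNifti::asNifti(vol)
  RNifti::pixdim(nif) <- voxelSize
  RNifti::writeNifti(nif, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Scenario / model configuration (YAML)
## ---------------------------------------------------------------------------

#' Read a scenario configuration from YAML
#'
#' Recognized blocks: \code{scenario} (name), \code{seed}, \code{noise}
#' (level), \code{input_function} (A1, A2, lambda1, lambda2, delay),
#' \code{rate_constants} (per-region maps of K1, k2, k3, KH, k4, k5) and
#' \code{ph_response} (ph50, hill, floor, ceiling) with optional
#' \code{region_ph}. Omitted blocks fall back to the named scenario's
#' defaults.
#'
#' @param path YAML file path.
#' @return A [ScenarioSpec-class].
#' @export
readScenarioConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  name <- if (!is.null(cfg$scenario)) cfg$scenario else "healthy"
  input <- NULL
  if (!is.null(cfg$input_function)) {
    ia <- cfg$input_function
    input <- inputFunction(A1 = ia$A1, A2 = ia$A2, lambda1 = ia$lambda1,
                           lambda2 = ia$lambda2,
                           delay = if (is.null(ia$delay)) 0 else ia$delay)
  }
  regions <- NULL
  if (!is.null(cfg$rate_constants)) {
    regions <- lapply(cfg$rate_constants, function(r) {
      rateConstants(K1 = r$K1, k2 = r$k2, k3 = r$k3, KH = r$KH,
                    k4 = if (is.null(r$k4)) 0 else r$k4,
                    k5 = if (is.null(r$k5)) 1.74 else r$k5)
    })
  }
  regionPH <- if (!is.null(cfg$region_ph)) unlist(cfg$region_ph) else NULL
  scenarioSpec(name,
               noiseLevel = if (is.null(cfg$noise)) 0 else cfg$noise,
               seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
               regions = regions, input = input, regionPH = regionPH)
}

#' Write a scenario configuration to YAML
#'
#' Serializes a [ScenarioSpec-class] so that
#' \code{readScenarioConfig(writeScenarioConfig(spec, f))} round-trips
#' losslessly.
#'
#' @param spec a [ScenarioSpec-class].
#' @param path output YAML path.
#' @return The path, invisibly.
#' @export
writeScenarioConfig <- function(spec, path) {
  stopifnot(is(spec, "ScenarioSpec"))
  cfg <- list(
    scenario = spec@name,
    seed = spec@seed,
    noise = spec@noiseLevel,
    input_function = list(A1 = spec@input@A1, A2 = spec@input@A2,
                          lambda1 = spec@input@lambda1,
                          lambda2 = spec@input@lambda2,
                          delay = spec@input@delay),
    rate_constants = lapply(spec@regions, function(r)
      list(K1 = r@K1, k2 = r@k2, k3 = r@k3, KH = r@KH, k4 = r@k4,
           k5 = r@k5)))
  if (length(spec@regionPH)) cfg$region_ph <- as.list(spec@regionPH)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
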