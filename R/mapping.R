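## Voxel-wise relative-K_H mapping: average an early uptake block
## (apparent maximum) and a late washout block, subtract, and divide by
## the early average. The resulting relative efflux fraction increases
## monotonically with the underlying hydrolysis rate and is invariant to
## global intensity scaling.

.flattenFrames <- function(img) {
  d <- dim(img@data)
  matrix(img@data, nrow = prod(d[1:3]), ncol = d[4L])
}

#' Relative hydrolysis-rate parametric map
#'
#' Four-step map arithmetic on a dynamic image: (1) average the early
#' frames (apparent maximum uptake), (2) average the late frames,
#' (3) subtract late from early (total washed-out volume), (4) divide by
#' the early average. Frame indices are 1-based on the 26-frame default
#' schedule: early = frames 3-10 (nominally 2-15 min), late = frames
#' 11-26 (nominally 15-90 min). Voxels whose early average does not
#' exceed \code{maskThreshold} are masked out (NaN) and counted; very low
#' delivery makes the ratio unreliable. Negative map values (net late
#' accumulation, as for a non-hydrolyzable probe) are preserved.
#'
#' @param img a [DynamicImage-class].
#' @param earlyFrames 1-based early frame indices; default 3:10.
#' @param lateFrames 1-based late frame indices; default 11:26.
#' @param maskThreshold early-mean validity threshold (SUV); default 0.2.
#' @param smoothFWHM optional isotropic Gaussian smoothing FWHM in mm
#'   applied to each frame before averaging; default 0 (off).
#' @return A [RelativeKHMap-class].
#' @export
relativeKHMap <- function(img, earlyFrames = 3:10, lateFrames = 11:26,
                          maskThreshold = 0.2, smoothFWHM = 0) {
  stopifnot(is(img, "DynamicImage"))
  nf <- nFrames(img@schedule)
  if (any(earlyFrames < 1L) || any(earlyFrames > nf) ||
      any(lateFrames < 1L) || any(lateFrames > nf))
    stop("frame indices out of range for the schedule")
  data <- img@data
  if (smoothFWHM > 0) {
    sigma <- smoothFWHM / (2 * sqrt(2 * log(2))) / img@voxelSize
    for (f in seq_len(nf))
      data[, , , f] <- .gaussianSmooth3D(data[, , , f], sigma)
  }
  d <- dim(data)
  mat <- matrix(data, nrow = prod(d[1:3]), ncol = d[4L])
  mEarly <- rowMeans(mat[, earlyFrames, drop = FALSE])
  mLate <- rowMeans(mat[, lateFrames, drop = FALSE])
  mask <- mEarly > maskThreshold
  mapv <- rep(NaN, length(mEarly))
  mapv[mask] <- (mEarly[mask] - mLate[mask]) / mEarly[mask]
  new("RelativeKHMap",
      map = array(mapv, dim = d[1:3]),
      mask = array(mask, dim = d[1:3]),
      threshold = as.numeric(maskThreshold),
      nMasked = sum(!mask))
}

## separable Gaussian smoothing along each axis (sigma in voxels)
.gaussianSmooth3D <- function(vol, sigma) {
  smooth1 <- function(x, s) {
    if (s <= 0) return(x)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2)); k <- k / sum(k)
    n <- length(x)
    xp <- c(rep(x[1L], r), x, rep(x[n], r))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
  }
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    vol <- apply(vol, setdiff(1:3, ax), smooth1, s = sigma[ax])
    vol <- aperm(vol, order(c(ax, setdiff(1:3, ax))))
  }
  vol
}

#' Extract a region-of-interest TAC
#'
#' Per-frame unweighted mean of the voxel values inside a mask.
#'
#' @param img a [DynamicImage-class].
#' @param mask logical or 0/1 numeric array on the image grid.
#' @return A [TimeActivityCurve-class].
#' @export
extractRoiTac <- function(img, mask) {
  stopifnot(is(img, "DynamicImage"))
  d <- dim(img@data)
  if (!identical(dim(mask), d[1:3]))
    stop("mask must share the image's 3D grid")
  idx <- which(as.logical(mask != 0))
  if (!length(idx)) stop("mask is empty")
  mat <- .flattenFrames(img)
  timeActivityCurve(img@schedule, colMeans(mat[idx, , drop = FALSE]))
}

#' Regional summary of a relative-K_H map
#'
#' Mean and SD of map values over each region, restricted to voxels inside
#' the map's validity mask. Regions that fall entirely outside the
#' validity mask are flagged.
#'
#' @param map a [RelativeKHMap-class].
#' @param masks named list of logical/0-1 arrays on the map grid, or a
#'   single integer label array (labels > 0 become regions).
#' @return A data.frame with columns region, n, mean, sd, flagged.
#' @export
mapRegionSummary <- function(map, masks) {
  stopifnot(is(map, "RelativeKHMap"))
  if (!is.list(masks)) {
    labs <- sort(unique(as.integer(masks[masks > 0])))
    masks <- stats::setNames(
      lapply(labs, function(l) masks == l),
      paste0("region", labs))
  }
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!identical(dim(m), dim(map@map)))
      stop(sprintf("mask '%s' does not match the map grid", nm))
    valid <- as.logical(m != 0) & map@mask
    n <- sum(valid)
    data.frame(region = nm, n = n,
               mean = if (n) mean(map@map[valid]) else NA_real_,
               sd = if (n > 1L) stats::sd(map@map[valid]) else
                 if (n == 1L) 0 else NA_real_,
               flagged = n == 0L)
  })
  do.call(rbind, rows)
}
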