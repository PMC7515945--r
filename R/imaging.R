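# Deterministic image-processing chain: binning, gamma-strike suppression,
# background subtraction, radiance calibration.

#' Construct acquisition settings
#'
#' @param exposure exposure time (s), > 0; the clinical protocol used
#'   30, 60, 150 and 300 s
#' @param binning binning factor (>= 1); clinical protocol used 2, 4, 8
#' @param filter "none" or "shortpass_550"
#' @param unbinnedPitch unbinned pixel pitch (um); the binned pitch is
#'   `unbinnedPitch * binning` (117 um unbinned so that 2x2 gives 234 um)
#' @return an [AcquisitionSettings-class]
#' @examples
#' acquisitionSettings(150, 8, "shortpass_550")
#' @export
acquisitionSettings <- function(exposure, binning = 1L, filter = "none",
                                unbinnedPitch = 117) {
  new("AcquisitionSettings", exposure = exposure,
      binning = as.integer(binning), filter = filter,
      pixelPitch = unbinnedPitch * as.integer(binning))
}

.settingsMatch <- function(a, b) {
  isTRUE(all.equal(a@exposure, b@exposure)) && a@binning == b@binning &&
    a@filter == b@filter
}

.appendHistory <- function(frame, op) {
  frame@history <- c(frame@history, op)
  frame
}

#' Bin pixels by summation
#'
#' Sums `factor` x `factor` blocks of the raster; the pixel pitch scales by
#' `factor` and total counts over the covered area are conserved. When the
#' raster dimensions are not divisible by `factor`, trailing rows/columns
#' are cropped (never padded).
#'
#' @param frame a [CLIFrame-class]
#' @param factor integer >= 1
#' @return the binned [CLIFrame-class]
#' @export
binPixels <- function(frame, factor) {
  if (factor < 1) stop("binning factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(frame)
  x <- frame@counts
  nrb <- nrow(x) %/% factor; ncb <- ncol(x) %/% factor
  if (nrb < 1L || ncb < 1L) stop("raster smaller than one bin")
  x <- x[seq_len(nrb * factor), seq_len(ncb * factor), drop = FALSE]
  dim(x) <- c(factor, nrb, factor, ncb)
  frame@counts <- colSums(colSums(aperm(x, c(1, 3, 2, 4))))
  frame@settings <- new("AcquisitionSettings",
                        exposure = frame@settings@exposure,
                        binning = frame@settings@binning * factor,
                        filter = frame@settings@filter,
                        pixelPitch = frame@settings@pixelPitch * factor)
  .appendHistory(frame, sprintf("bin_%dx%d", factor, factor))
}

#' Suppress gamma strikes
#'
#' Removes the sparse high-amplitude impulses caused by gamma photons
#' hitting the sensor directly, with a `medianWindow` x `medianWindow`
#' median filter followed by Gaussian smoothing (`gaussianSigma` pixels) of
#' the residual, the on-device processing applied to every displayed CLI
#' image. The median runs first so impulses are eliminated before the
#' linear filter could spread them; both filters use reflect boundary
#' handling, so a constant raster is reproduced exactly and the raster
#' maximum never increases.
#'
#' @param frame a [CLIFrame-class]
#' @param medianWindow odd window size (pixels), default 3
#' @param gaussianSigma Gaussian sigma (pixels), default 3; 0 disables
#'   smoothing
#' @param order "median_first" (default) or "gaussian_first"
#' @return the filtered [CLIFrame-class] (values may be non-integer)
#' @export
suppressGammaStrikes <- function(frame, medianWindow = 3L, gaussianSigma = 3,
                                 order = c("median_first", "gaussian_first")) {
  order <- match.arg(order)
  medianWindow <- as.integer(medianWindow)
  if (medianWindow < 1L || medianWindow %% 2L == 0L)
    stop("medianWindow must be odd and >= 1")
  if (gaussianSigma < 0) stop("gaussianSigma must be >= 0")
  k <- .gaussKernel(gaussianSigma)
  x <- frame@counts
  if (order == "median_first") {
    x <- .medianFilter(x, medianWindow)
    x <- .convolveSeparable(x, k)
  } else {
    x <- .convolveSeparable(x, k)
    x <- .medianFilter(x, medianWindow)
  }
  frame@counts <- pmax(x, 0)
  .appendHistory(frame,
                 sprintf("suppress_strikes(median%d,gauss%g,%s)",
                         medianWindow, gaussianSigma, order))
}

#' Subtract a settings-matched background frame
#'
#' Pixel-wise subtraction of an empty-tray background acquired with the
#' same exposure, binning and filter — the step that removes the dark
#' offset and the defective-pixel artefact. Mismatched settings are a
#' contract violation and raise an error. Negative differences are clamped
#' to zero by default (radiance is physical); `clamp = FALSE` keeps signed
#' values for diagnostics (the frame is then returned with the negatives
#' shifted into meta$signed).
#'
#' @param frame specimen [CLIFrame-class]
#' @param background background [CLIFrame-class] with identical settings
#'   and shape
#' @param clamp clamp negatives to 0 (default TRUE)
#' @return the background-subtracted [CLIFrame-class]
#' @export
subtractBackground <- function(frame, background, clamp = TRUE) {
  if (!.settingsMatch(frame@settings, background@settings))
    stop("background settings (exposure/binning/filter) must match the frame; ",
         "a background acquired with the same settings is required")
  if (!all(dim(frame@counts) == dim(background@counts)))
    stop("frame and background shapes differ")
  d <- frame@counts - background@counts
  if (clamp) {
    frame@counts <- pmax(d, 0)
  } else {
    frame@counts <- pmax(d, 0)
    frame@meta$signed <- d
  }
  .appendHistory(frame, "subtract_background")
}

#' Convert counts to calibrated radiance
#'
#' Linear conversion `radiance = counts / (calibration * exposure)` per
#' binned pixel, yielding p/s/cm2/sr. The default calibration of 1 leaves
#' arbitrary-units radiance; all TBRs are invariant to this constant.
#'
#' @param frame a [CLIFrame-class]
#' @param calibration counts per (p/s/cm2/sr) s pixel, > 0
#' @param calibrationId label recorded in the map
#' @return a [RadianceMap-class]
#' @export
countsToRadiance <- function(frame, calibration = 1,
                             calibrationId = "arbitrary_units") {
  if (calibration <= 0) stop("calibration must be > 0")
  if (length(frame@settings@exposure) != 1L || frame@settings@exposure <= 0)
    stop("frame exposure unknown or invalid")
  new("RadianceMap",
      values = frame@counts / (calibration * frame@settings@exposure),
      settings = frame@settings, acquisitionTime = frame@acquisitionTime,
      view = frame@view, calibrationId = calibrationId,
      history = c(frame@history, "counts_to_radiance"))
}

#' Full frame-to-radiance processing chain
#'
#' Convenience wrapper running the standard chain on an acquired frame:
#' gamma-strike suppression (median then Gaussian) on both the specimen
#' frame and its settings-matched background, background subtraction, and
#' radiance calibration.
#'
#' @inheritParams subtractBackground
#' @inheritParams countsToRadiance
#' @param medianWindow,gaussianSigma see [suppressGammaStrikes()]
#' @return a [RadianceMap-class]
#' @export
processFrame <- function(frame, background, medianWindow = 3L,
                         gaussianSigma = 3, calibration = 1) {
  f <- suppressGammaStrikes(frame, medianWindow, gaussianSigma)
  b <- suppressGammaStrikes(background, medianWindow, gaussianSigma)
  countsToRadiance(subtractBackground(f, b), calibration)
}
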