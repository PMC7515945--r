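# ROI radiance quantification, decay/activity correction, TBR, cohort
# summaries.

#' Construct an ROI from pixel coordinates
#'
#' @param pixels n x 2 integer matrix of (row, col) on the binned grid
#' @param label "tumour" or "background"
#' @param view view the ROI belongs to
#' @return an [ROI-class]
#' @export
roi <- function(pixels, label = "tumour", view = "") {
  new("ROI", pixels = matrix(as.integer(pixels), ncol = 2), label = label,
      view = view)
}

#' Construct an ROI from a logical mask
#'
#' @param mask logical matrix on the binned grid
#' @inheritParams roi
#' @return an [ROI-class]
#' @export
roiFromMask <- function(mask, label = "tumour", view = "") {
  roi(which(mask, arr.ind = TRUE), label = label, view = view)
}

#' Construct an ROI from a polygon
#'
#' Rasterizes a (row, col) polygon by the even-odd rule with pixel-centre
#' inclusion.
#'
#' @param polygon n x 2 numeric matrix of (row, col) vertices
#' @param dim raster dimensions c(rows, cols)
#' @inheritParams roi
#' @return an [ROI-class]
#' @export
roiFromPolygon <- function(polygon, dim, label = "tumour", view = "") {
  roiFromMask(.rasterizePolygon(polygon, dim[1], dim[2]), label = label,
              view = view)
}

#' Automatic background ROI for synthetic benchmarking
#'
#' Derives a benign-tissue ROI as the pixels in the lowest quantile band of
#' the map, a stand-in for the manually drawn "no increased signal" region
#' of the clinical workflow (supplied-masks remain the primary interface).
#'
#' @param map a [RadianceMap-class]
#' @param quantile upper quantile bound of included pixels (default 0.5:
#'   the dimmer half of the image)
#' @return a background [ROI-class]
#' @export
autoBackgroundROI <- function(map, quantile = 0.5) {
  q <- stats::quantile(map@values, quantile)
  roiFromMask(map@values <= q, label = "background", view = map@view)
}

#' Mean radiance over an ROI
#'
#' Arithmetic mean of the radiance map over the ROI mask.
#'
#' @param map a [RadianceMap-class]
#' @param roi an [ROI-class] within the map bounds
#' @return mean radiance (p/s/cm2/sr)
#' @export
roiMeanRadiance <- function(map, roi) {
  stopifnot(is(map, "RadianceMap"), is(roi, "ROI"))
  px <- roi@pixels
  if (nrow(px) == 0) stop("empty ROI")
  if (any(px < 1) || any(px[, 1] > nrow(map@values)) ||
      any(px[, 2] > ncol(map@values)))
    stop("ROI pixel out of raster bounds")
  mean(map@values[px])
}

#' Decay-correct a radiance to injection time
#'
#' Rescales a measured radiance back to the injection timestamp:
#' `radiance * 2^(elapsed / halfLife)`, the inverse of [decayFactor()].
#'
#' @param radiance measured mean radiance (p/s/cm2/sr)
#' @param acquisitionTime frame timestamp (POSIXct), not before injection
#' @param injectionTime injection timestamp (POSIXct)
#' @param halfLife isotope half-life (minutes)
#' @return decay-corrected radiance
#' @examples
#' t0 <- as.POSIXct("2020-01-01 09:00:00", tz = "UTC")
#' decayCorrect(100, t0 + 68 * 60, t0, 68)  # 200
#' @export
decayCorrect <- function(radiance, acquisitionTime, injectionTime,
                         halfLife = 68) {
  elapsed <- .minutesBetween(acquisitionTime, injectionTime)
  if (any(elapsed < 0)) stop("acquisition before injection")
  radiance * 2^(elapsed / halfLife)
}

#' Normalize a decay-corrected radiance to a reference activity
#'
#' `decayCorrected * referenceActivity / injectedActivity`, enabling
#' comparison between patients injected with different activities while
#' keeping p/s/cm2/sr units. The protocol's nominal injection of ~100 MBq
#' is the default reference.
#'
#' @param decayCorrected decay-corrected radiance (p/s/cm2/sr)
#' @param injectedActivity injected activity (MBq), > 0
#' @param referenceActivity reference activity (MBq), > 0
#' @return activity-corrected radiance
#' @export
activityNormalize <- function(decayCorrected, injectedActivity,
                              referenceActivity = 100) {
  if (any(injectedActivity <= 0) || any(referenceActivity <= 0))
    stop("activities must be > 0")
  decayCorrected * referenceActivity / injectedActivity
}

#' Measure an ROI on a radiance map with all corrections
#'
#' Returns the raw ROI mean radiance together with its decay-corrected and
#' activity-corrected values, the full record behind one cell of a
#' per-patient quantification table.
#'
#' @inheritParams roiMeanRadiance
#' @inheritParams decayCorrect
#' @inheritParams activityNormalize
#' @return list with `raw`, `decayCorrected`, `activityCorrected`,
#'   `elapsedMinutes`, `label`, `view`
#' @export
measureROI <- function(map, roi, injectionTime, halfLife = 68,
                       injectedActivity = 100, referenceActivity = 100) {
  raw <- roiMeanRadiance(map, roi)
  dc <- decayCorrect(raw, map@acquisitionTime, injectionTime, halfLife)
  ac <- activityNormalize(dc, injectedActivity, referenceActivity)
  list(raw = raw, decayCorrected = dc, activityCorrected = ac,
       elapsedMinutes = .minutesBetween(map@acquisitionTime, injectionTime),
       label = roi@label, view = roi@view)
}

#' Tumour-to-background ratio
#'
#' Ratio of tumour to background mean radiance from the same frame. The
#' ratio is invariant under any common positive scaling — calibration,
#' decay correction and activity normalization all cancel.
#'
#' @param tumour tumour mean radiance, or a [measureROI()] record
#' @param background background mean radiance (> 0), or a [measureROI()]
#'   record from the same frame
#' @return dimensionless TBR
#' @export
tbr <- function(tumour, background) {
  tv <- if (is.list(tumour)) tumour$raw else tumour
  bv <- if (is.list(background)) background$raw else background
  if (is.list(tumour) && is.list(background)) {
    if (!identical(tumour$view, background$view) ||
        !isTRUE(all.equal(tumour$elapsedMinutes, background$elapsedMinutes)))
      stop("tumour and background measurements must come from the same frame")
  }
  if (bv <= 0) stop("background radiance must be > 0")
  tv / bv
}

#' Cohort mean and dispersion
#'
#' Arithmetic mean and population standard deviation (divisor n), the
#' dispersion convention that reproduces clinical cohort tables of the form
#' "mean +/- sd"; `sample = TRUE` switches to the n-1 divisor.
#'
#' @param values non-empty numeric vector
#' @param sample use the sample (n-1) standard deviation
#' @return named numeric c(mean, sd)
#' @examples
#' cohortSummary(c(118, 68, 88, 76, 65))  # 83 +/- 19
#' @export
cohortSummary <- function(values, sample = FALSE) {
  if (length(values) == 0) stop("empty value list")
  m <- mean(values)
  v <- sum((values - m)^2) / (if (sample) length(values) - 1 else length(values))
  c(mean = m, sd = sqrt(v))
}
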