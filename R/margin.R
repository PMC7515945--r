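# Hotspot detection and the filtered/unfiltered persistence rule for
# calling a suspected positive surgical margin.

#' Background statistics of a radiance map
#'
#' Mean and standard deviation of the benign-tissue background, estimated
#' from the pixels at or below the given quantile (the dimmer part of the
#' image). A supplied background ROI may be used instead via
#' [roiMeanRadiance()]; this helper is the automatic surrogate used in
#' synthetic benchmarks.
#'
#' @param map a [RadianceMap-class]
#' @param quantile upper quantile bound of included pixels
#' @return named numeric c(mean, sd)
#' @export
backgroundStats <- function(map, quantile = 0.5) {
  v <- map@values[map@values <= stats::quantile(map@values, quantile)]
  c(mean = mean(v), sd = stats::sd(v))
}

#' Detect hotspots on a radiance map
#'
#' Algorithmic surrogate for the visual hotspot marking of the clinical
#' workflow: 4-connected components of pixels above
#' `mean + kSigma * sd` of the background, retained when their area is at
#' least `minArea` pixels. Because the detection threshold sits just above
#' the background, a smooth hotspot's component includes its faint tail;
#' TBR is therefore measured over the component's half-maximum core (the
#' pixels whose background-subtracted value reaches half the peak's), the
#' compact ROI a reader would draw around the hotspot. A degenerate
#' background (sd = 0 with a flat map) yields an empty list.
#'
#' @param map a [RadianceMap-class]
#' @param bgStats named numeric c(mean, sd) as from [backgroundStats()]
#' @param kSigma detection threshold in background sds (default 3)
#' @param minArea minimum component area in binned pixels (default 4)
#' @return list of [Hotspot-class]
#' @export
detectHotspots <- function(map, bgStats = backgroundStats(map), kSigma = 3,
                           minArea = 4L) {
  if (bgStats[["sd"]] < 0) stop("background sd must be >= 0")
  if (minArea < 1) stop("minArea must be >= 1")
  thr <- bgStats[["mean"]] + kSigma * bgStats[["sd"]]
  mask <- map@values > thr
  if (!any(mask)) return(list())
  labels <- .labelComponents4(mask)
  out <- list()
  for (id in seq_len(max(labels))) {
    px <- which(labels == id, arr.ind = TRUE)
    if (nrow(px) < minArea) next
    vals <- map@values[px]
    peak <- max(vals)
    core <- px[vals >= bgStats[["mean"]] + 0.5 * (peak - bgStats[["mean"]]), ,
               drop = FALSE]
    out[[length(out) + 1L]] <- new("Hotspot", view = map@view, pixels = px,
                                   corePixels = core,
                                   peakRadiance = peak,
                                   tbrUnfiltered = mean(map@values[core]) /
                                     bgStats[["mean"]],
                                   tbrFiltered = NA_real_,
                                   persistent = FALSE)
  }
  out
}

#' Match a hotspot on the shortpass-filtered map
#'
#' Annotates a hotspot detected on the unfiltered image with its TBR over
#' the same half-maximum core pixels on the filtered map, and flags it
#' persistent when
#' that filtered TBR reaches `tauPersist`. Because sub-550 nm light is
#' strongly attenuated by tissue, a hotspot that persists on the filtered
#' image indicates PSMA-avid cells near the excision surface; a hotspot
#' that vanishes indicates signal from deeper tissue.
#'
#' @param hotspot a [Hotspot-class] from the unfiltered map
#' @param filteredMap the [RadianceMap-class] of the same view acquired
#'   with the shortpass filter (same geometry)
#' @param bgStatsFiltered background c(mean, sd) of the filtered map
#' @param tauPersist filtered-TBR persistence threshold (default 2)
#' @return the annotated [Hotspot-class]
#' @export
matchFiltered <- function(hotspot, filteredMap,
                          bgStatsFiltered = backgroundStats(filteredMap),
                          tauPersist = 2) {
  if (nzchar(hotspot@view) && nzchar(filteredMap@view) &&
      hotspot@view != filteredMap@view)
    stop("filtered map view does not match the hotspot's view")
  if (any(hotspot@pixels[, 1] > nrow(filteredMap@values)) ||
      any(hotspot@pixels[, 2] > ncol(filteredMap@values)))
    stop("filtered map geometry does not match the hotspot's source map")
  if (bgStatsFiltered[["mean"]] <= 0)
    stop("filtered background mean must be > 0")
  tf <- mean(filteredMap@values[hotspot@corePixels]) / bgStatsFiltered[["mean"]]
  hotspot@tbrFiltered <- tf
  hotspot@persistent <- tf >= tauPersist
  hotspot
}

#' Classify one specimen view
#'
#' Applies the persistence rule to a view: hotspots are detected on the
#' unfiltered map, each is matched on the filtered map, and the verdict is
#' "PSM_suspected" exactly when at least one hotspot persists. With no
#' filtered acquisition available the verdict falls back to the unfiltered
#' TBR against `tauPersist` and is flagged low-confidence in the rationale.
#'
#' @param unfilteredMap [RadianceMap-class] acquired without a filter
#' @param filteredMap [RadianceMap-class] with the shortpass filter, or
#'   NULL when none was acquired
#' @param kSigma,minArea see [detectHotspots()]
#' @param tauPersist see [matchFiltered()]
#' @return a [MarginCall-class]
#' @export
classifyView <- function(unfilteredMap, filteredMap, kSigma = 3,
                         minArea = 4L, tauPersist = 2) {
  hs <- detectHotspots(unfilteredMap, kSigma = kSigma, minArea = minArea)
  view <- unfilteredMap@view
  if (length(hs) == 0)
    return(new("MarginCall", view = view, verdict = "NSM", hotspots = list(),
               rationale = "no hotspot detected on the unfiltered image"))
  if (is.null(filteredMap)) {
    hs <- lapply(hs, function(h) {
      h@persistent <- h@tbrUnfiltered >= tauPersist
      h
    })
    v <- if (any(vapply(hs, isPersistent, logical(1)))) "PSM_suspected" else "NSM"
    return(new("MarginCall", view = view, verdict = v, hotspots = hs,
               rationale = paste("LOW CONFIDENCE: no filtered acquisition;",
                                 "verdict from unfiltered TBR only")))
  }
  bgF <- backgroundStats(filteredMap)
  hs <- lapply(hs, matchFiltered, filteredMap = filteredMap,
               bgStatsFiltered = bgF, tauPersist = tauPersist)
  if (any(vapply(hs, isPersistent, logical(1))))
    new("MarginCall", view = view, verdict = "PSM_suspected", hotspots = hs,
        rationale = "persistent hotspot on the shortpass-filtered image")
  else
    new("MarginCall", view = view, verdict = "NSM", hotspots = hs,
        rationale = paste("non-persistent hotspot: signal vanishes on the",
                          "filtered image (activity below the surface)"))
}

#' Specimen-level verdict
#'
#' OR over the per-view calls: any view with a suspected PSM makes the
#' specimen PSM-suspected, matching a single per-patient margin row.
#'
#' @param calls list of [MarginCall-class]
#' @return "PSM_suspected" or "NSM"
#' @export
classifySpecimen <- function(calls) {
  if (any(vapply(calls, verdict, character(1)) == "PSM_suspected"))
    "PSM_suspected" else "NSM"
}

#' Score margin calls against ground truth
#'
#' Confusion counts of per-view verdicts against ground-truth labels.
#' Views whose truth is "CLOSE" (tumour within 0.1 mm of the surface) are
#' tallied separately rather than as plain false positives: hotspots from
#' near-margin tumour are expected physics (positron range, optical blur),
#' not classifier errors.
#'
#' @param calls list of [MarginCall-class], one per truth view
#' @param truthLabels named character vector (names = views) with values
#'   in "PSM", "CLOSE", "NSM", e.g. `groundTruth(study)$labels`
#' @return named integer vector: TP, FP, TN, FN, CLOSE_called,
#'   CLOSE_not_called
#' @export
evaluateAgainstTruth <- function(calls, truthLabels) {
  views <- vapply(calls, viewLabel, character(1))
  if (!setequal(views, names(truthLabels)) ||
      length(views) != length(truthLabels))
    stop("calls and truth must cover the same views exactly once")
  out <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L,
           CLOSE_called = 0L, CLOSE_not_called = 0L)
  for (call in calls) {
    truth <- truthLabels[[viewLabel(call)]]
    called <- verdict(call) == "PSM_suspected"
    if (truth == "PSM") {
      out[if (called) "TP" else "FN"] <- out[if (called) "TP" else "FN"] + 1L
    } else if (truth == "NSM") {
      out[if (called) "FP" else "TN"] <- out[if (called) "FP" else "TN"] + 1L
    } else if (truth == "CLOSE") {
      key <- if (called) "CLOSE_called" else "CLOSE_not_called"
      out[key] <- out[key] + 1L
    } else stop("unknown truth label: ", truth)
  }
  out
}
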