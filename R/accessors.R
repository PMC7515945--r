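#' @describeIn cliMargin-generics photon counts of a [CLIFrame-class]
#' @export
setMethod("counts", "CLIFrame", function(object) object@counts)

#' @describeIn cliMargin-generics radiance raster of a [RadianceMap-class]
#' @export
setMethod("radianceValues", "RadianceMap", function(object) object@values)

#' @describeIn cliMargin-generics settings of a frame
#' @export
setMethod("acqSettings", "CLIFrame", function(object) object@settings)

#' @describeIn cliMargin-generics settings of a radiance map
#' @export
setMethod("acqSettings", "RadianceMap", function(object) object@settings)

#' @describeIn cliMargin-generics exposure (s)
#' @export
setMethod("exposureTime", "AcquisitionSettings", function(object) object@exposure)

#' @describeIn cliMargin-generics exposure (s) of a frame
#' @export
setMethod("exposureTime", "CLIFrame", function(object) object@settings@exposure)

#' @describeIn cliMargin-generics exposure (s) of a radiance map
#' @export
setMethod("exposureTime", "RadianceMap", function(object) object@settings@exposure)

#' @describeIn cliMargin-generics binning factor
#' @export
setMethod("binningFactor", "AcquisitionSettings", function(object) object@binning)

#' @describeIn cliMargin-generics binning factor of a frame
#' @export
setMethod("binningFactor", "CLIFrame", function(object) object@settings@binning)

#' @describeIn cliMargin-generics optical filter label
#' @export
setMethod("opticalFilter", "AcquisitionSettings", function(object) object@filter)

#' @describeIn cliMargin-generics optical filter of a frame
#' @export
setMethod("opticalFilter", "CLIFrame", function(object) object@settings@filter)

#' @describeIn cliMargin-generics acquisition start time
#' @export
setMethod("acquisitionTime", "CLIFrame", function(object) object@acquisitionTime)

#' @describeIn cliMargin-generics acquisition start time of a map
#' @export
setMethod("acquisitionTime", "RadianceMap", function(object) object@acquisitionTime)

#' @describeIn cliMargin-generics "specimen" or "background"
#' @export
setMethod("frameKind", "CLIFrame", function(object) object@kind)

#' @describeIn cliMargin-generics view label of a frame
#' @export
setMethod("viewLabel", "CLIFrame", function(object) object@view)

#' @describeIn cliMargin-generics view label of a map
#' @export
setMethod("viewLabel", "RadianceMap", function(object) object@view)

#' @describeIn cliMargin-generics view label of a hotspot
#' @export
setMethod("viewLabel", "Hotspot", function(object) object@view)

#' @describeIn cliMargin-generics view label of a margin call
#' @export
setMethod("viewLabel", "MarginCall", function(object) object@view)

#' @describeIn cliMargin-generics provenance of a frame
#' @export
setMethod("processingHistory", "CLIFrame", function(object) object@history)

#' @describeIn cliMargin-generics provenance of a map
#' @export
setMethod("processingHistory", "RadianceMap", function(object) object@history)

#' @describeIn cliMargin-generics metadata list of a frame
#' @export
setMethod("frameMeta", "CLIFrame", function(object) object@meta)

#' @describeIn cliMargin-generics verdict of a margin call
#' @export
setMethod("verdict", "MarginCall", function(object) object@verdict)

#' @describeIn cliMargin-generics hotspot list of a margin call
#' @export
setMethod("hotspots", "MarginCall", function(object) object@hotspots)

#' @describeIn cliMargin-generics persistence flag of a hotspot
#' @export
setMethod("isPersistent", "Hotspot", function(object) object@persistent)

#' @describeIn cliMargin-generics pixel matrix of an ROI
#' @export
setMethod("roiPixels", "ROI", function(object) object@pixels)

#' @describeIn cliMargin-generics ground truth of a simulated study
#' @export
setMethod("groundTruth", "SpecimenStudy", function(object) object@groundTruth)

#' @describeIn cliMargin-generics manifest table of a study
#' @export
setMethod("studyManifest", "SpecimenStudy", function(object) object@manifest)

setMethod("show", "CLIFrame", function(object) {
  d <- dim(object@counts)
  cat(sprintf("CLIFrame [%s] %dx%d  view=%s  %gs  %dx%d binning  filter=%s\n",
              object@kind, d[1], d[2],
              if (nzchar(object@view)) object@view else "-",
              object@settings@exposure, object@settings@binning,
              object@settings@binning, object@settings@filter))
  cat(sprintf("  counts: [%g, %g]  acquired %s\n", min(object@counts),
              max(object@counts),
              format(object@acquisitionTime, "%Y-%m-%d %H:%M:%S %Z")))
  if (length(object@history))
    cat("  history:", paste(object@history, collapse = " -> "), "\n")
})

setMethod("show", "RadianceMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("RadianceMap %dx%d  view=%s  filter=%s  [%0.4g, %0.4g] p/s/cm2/sr\n",
              d[1], d[2], if (nzchar(object@view)) object@view else "-",
              object@settings@filter, min(object@values), max(object@values)))
})

setMethod("show", "Isotope", function(object) {
  cat(sprintf("Isotope %s: T1/2 = %g min, endpoint %g keV, mean range %g mm, branching %g (%s)\n",
              object@name, object@halfLife, object@endpointEnergy,
              object@meanPositronRange, object@branchingFraction,
              object@particle))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d lesion(s), benign %g p/s/cm2/sr @ %g MBq ref, injected %g MBq (%s)\n",
              length(object@lesions), object@benignRadiance,
              object@referenceActivity, object@injectedActivity,
              object@isotope@name))
  for (l in object@lesions)
    cat(sprintf("  lesion view=%s depth=%g mm ratio=%g sigma=%g mm\n",
                l@view, l@depth, l@ratio, l@lateralSigma))
})

setMethod("show", "MarginCall", function(object) {
  cat(sprintf("MarginCall view=%s: %s (%d hotspot(s))\n", object@view,
              object@verdict, length(object@hotspots)))
  cat("  rationale:", object@rationale, "\n")
})

setMethod("show", "Hotspot", function(object) {
  cat(sprintf("Hotspot view=%s area=%d peak=%.4g TBR=%.2f filteredTBR=%s persistent=%s\n",
              object@view, nrow(object@pixels), object@peakRadiance,
              object@tbrUnfiltered,
              ifelse(is.na(object@tbrFiltered), "NA",
                     sprintf("%.2f", object@tbrFiltered)),
              object@persistent))
})

setMethod("show", "SpecimenStudy", function(object) {
  cat(sprintf("SpecimenStudy %s: %d specimen frame(s), %d background(s), %g MBq %s\n",
              object@patientId, length(object@frames),
              length(object@backgrounds), object@injectedActivity,
              object@isotopeName))
})
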