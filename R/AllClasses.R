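setOldClass(c("POSIXct", "POSIXt"))

#' Optical wavelength band with effective tissue attenuation
#'
#' A wavelength interval paired with the effective attenuation coefficient
#' of soft tissue over that interval. Short wavelengths (below ~550 nm)
#' attenuate much faster in tissue than red/near-infrared light, which is the
#' physical basis of shortpass-filtered margin assessment: signal surviving a
#' 550 nm shortpass filter must originate close to the specimen surface.
#'
#' @slot lower lower wavelength bound (nm)
#' @slot upper upper wavelength bound (nm)
#' @slot muEff effective attenuation coefficient in tissue (cm^-1)
#'
#' @seealso [opticalBand()], [tissueTransmission()]
#' @export
setClass("OpticalBand",
  representation(lower = "numeric", upper = "numeric", muEff = "numeric"),
  validity = function(object) {
    if (length(object@lower) != 1L || length(object@upper) != 1L ||
        length(object@muEff) != 1L)
      return("lower, upper and muEff must be scalars")
    if (!(object@lower > 0 && object@upper > object@lower))
      return("need 0 < lower < upper (nm)")
    if (object@muEff < 0) return("muEff must be >= 0")
    TRUE
  }
)

#' Beta-emitting isotope
#'
#' Physical constants of a positron (or electron) emitter as used by the
#' Cerenkov simulator: half-life, beta endpoint energy, mean positron range
#' in soft tissue, and the branching fraction into the beta channel.
#' `daughterZ` (atomic number of the daughter nucleus) and `particle`
#' ("beta+" or "beta-") parameterize the Fermi correction of the beta
#' spectrum shape.
#'
#' @slot name isotope label, e.g. "Ga-68"
#' @slot halfLife half-life in minutes
#' @slot endpointEnergy beta endpoint (maximum) kinetic energy in keV
#' @slot meanPositronRange mean positron range in soft tissue (mm)
#' @slot branchingFraction fraction of decays through the beta channel (0, 1]
#' @slot daughterZ atomic number of the daughter nucleus
#' @slot particle "beta+" or "beta-"
#'
#' @seealso [getIsotope()], [betaSpectrum()]
#' @export
setClass("Isotope",
  representation(name = "character", halfLife = "numeric",
                 endpointEnergy = "numeric", meanPositronRange = "numeric",
                 branchingFraction = "numeric", daughterZ = "numeric",
                 particle = "character"),
  validity = function(object) {
    if (object@halfLife <= 0) return("halfLife must be > 0")
    if (object@endpointEnergy <= 0) return("endpointEnergy must be > 0")
    if (object@meanPositronRange < 0) return("meanPositronRange must be >= 0")
    if (object@branchingFraction <= 0 || object@branchingFraction > 1)
      return("branchingFraction must be in (0, 1]")
    if (!object@particle %in% c("beta+", "beta-"))
      return("particle must be 'beta+' or 'beta-'")
    TRUE
  }
)

#' Beta decay energy spectrum
#'
#' Probability density of the beta particle kinetic energy on an ascending
#' energy grid, normalized to unit area and zero above the endpoint.
#'
#' @slot energy ascending kinetic-energy grid (keV)
#' @slot density probability density (per keV) at each grid point
#' @slot isotope name of the isotope the spectrum was built for
#' @export
setClass("BetaSpectrum",
  representation(energy = "numeric", density = "numeric",
                 isotope = "character"),
  validity = function(object) {
    if (length(object@energy) != length(object@density))
      return("energy and density must have equal length")
    if (is.unsorted(object@energy, strictly = TRUE))
      return("energy grid must be strictly ascending")
    if (any(object@density < 0)) return("density must be >= 0")
    area <- sum(diff(object@energy) *
                (object@density[-1] + object@density[-length(object@density)]) / 2)
    if (abs(area - 1) > 1e-6)
      return(sprintf("density must integrate to 1 (got %.8f)", area))
    TRUE
  }
)

#' Acquisition settings of a CLI frame
#'
#' @slot exposure exposure time in seconds
#' @slot binning on-sensor binning factor (1, 2, 4 or 8 in the clinical
#'   protocol; any integer >= 1 is accepted)
#' @slot filter optical filter: "none" or "shortpass_550"
#' @slot pixelPitch pitch of the binned pixel (micrometres)
#' @seealso [acquisitionSettings()]
#' @export
setClass("AcquisitionSettings",
  representation(exposure = "numeric", binning = "integer",
                 filter = "character", pixelPitch = "numeric"),
  validity = function(object) {
    if (object@exposure <= 0) return("exposure must be > 0 s")
    if (object@binning < 1L) return("binning must be >= 1")
    if (!object@filter %in% c("none", "shortpass_550"))
      return("filter must be 'none' or 'shortpass_550'")
    if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
    TRUE
  }
)

#' Photon-counting camera model for the CLI simulator
#'
#' Noise and artefact model of a cooled photon-counting CLI camera:
#' Gaussian read noise, constant dark offset, sparse high-amplitude gamma
#' strikes (annihilation photons hitting the sensor directly), a fixed
#' defective pixel rendered at full scale, and a linear radiance-to-count
#' conversion.
#'
#' @slot pixelPitch unbinned pixel pitch (micrometres)
#' @slot sensorShape integer c(rows, cols) of the unbinned sensor
#' @slot readNoiseSigma read noise standard deviation (counts, per unbinned
#'   pixel read)
#' @slot darkOffset constant dark offset (counts per unbinned pixel)
#' @slot gammaStrikeRate expected gamma strikes per frame per second
#' @slot gammaStrikeMean mean of the exponential strike-amplitude
#'   distribution (counts); amplitudes are truncated below 5x read noise
#' @slot defectivePixels integer matrix (n x 2) of (row, col) defective
#'   pixel coordinates on the unbinned grid
#' @slot countsPerRadiance counts per second per unbinned pixel produced by
#'   unit radiance (1 p/s/cm2/sr); the camera calibration constant
#' @slot bitDepth ADC bit depth; counts clip at 2^bitDepth - 1 after binning
#' @seealso [cameraModel()]
#' @export
setClass("CameraModel",
  representation(pixelPitch = "numeric", sensorShape = "integer",
                 readNoiseSigma = "numeric", darkOffset = "numeric",
                 gammaStrikeRate = "numeric", gammaStrikeMean = "numeric",
                 defectivePixels = "matrix", countsPerRadiance = "numeric",
                 bitDepth = "integer"),
  validity = function(object) {
    if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
    if (length(object@sensorShape) != 2L || any(object@sensorShape < 1L))
      return("sensorShape must be two positive integers")
    if (object@readNoiseSigma < 0 || object@darkOffset < 0 ||
        object@gammaStrikeRate < 0 || object@gammaStrikeMean < 0)
      return("noise parameters must be >= 0")
    dp <- object@defectivePixels
    if (nrow(dp) > 0) {
      if (ncol(dp) != 2L) return("defectivePixels must be an n x 2 matrix")
      if (any(dp < 1) || any(dp[, 1] > object@sensorShape[1]) ||
          any(dp[, 2] > object@sensorShape[2]))
        return("defective pixels must lie within the sensor")
    }
    if (object@countsPerRadiance <= 0) return("countsPerRadiance must be > 0")
    if (object@bitDepth < 1L) return("bitDepth must be >= 1")
    TRUE
  }
)

#' PSMA-avid lesion specification for the specimen phantom
#'
#' One surface-proximal lesion on one specimen view. `depth` is the distance
#' of the lesion below the excision surface: depth 0 corresponds to tumour at
#' the inked surface (a histopathological positive margin), depths below
#' 0.1 mm to the near-margin "close" band, larger depths to a negative
#' margin. `ratio` is the lesion:benign activity-concentration ratio, i.e.
#' the ground-truth tumour-to-background ratio before optical attenuation.
#'
#' @slot view one of "left", "right", "anterior", "posterior", "basal",
#'   "apical"
#' @slot center numeric c(row, col) lesion centre on the unbinned pixel grid
#' @slot lateralSigma lateral Gaussian extent of the lesion (mm)
#' @slot depth depth below the excision surface (mm)
#' @slot ratio lesion:benign uptake ratio (> 0), the true TBR
#' @seealso [lesionSpec()]
#' @export
setClass("LesionSpec",
  representation(view = "character", center = "numeric",
                 lateralSigma = "numeric", depth = "numeric",
                 ratio = "numeric"),
  validity = function(object) {
    if (!object@view %in% .cliViews())
      return(paste("view must be one of:", paste(.cliViews(), collapse = ", ")))
    if (length(object@center) != 2L) return("center must be c(row, col)")
    if (object@lateralSigma <= 0) return("lateralSigma must be > 0")
    if (object@depth < 0) return("depth must be >= 0")
    if (object@ratio <= 0) return("ratio must be > 0")
    TRUE
  }
)

#' Ground-truthed synthetic specimen phantom
#'
#' Complete specification of a synthetic six-view CLI specimen study:
#' lesion geometry, benign surface radiance at the reference activity,
#' injected activity and injection time, isotope, camera model, and the
#' unfiltered/filtered optical bands.
#'
#' @slot lesions list of [LesionSpec-class] objects
#' @slot benignRadiance benign-tissue surface radiance (p/s/cm2/sr) at the
#'   reference injected activity, at injection time
#' @slot injectedActivity injected activity (MBq)
#' @slot referenceActivity reference activity for inter-patient
#'   normalization (MBq)
#' @slot injectionTime injection timestamp (POSIXct)
#' @slot isotope [Isotope-class]
#' @slot camera [CameraModel-class]
#' @slot unfilteredBand [OpticalBand-class] seen without a filter
#' @slot filteredBand [OpticalBand-class] transmitted by the shortpass filter
#' @seealso [phantomSpec()], [renderView()], [renderStudy()]
#' @export
setClass("PhantomSpec",
  representation(lesions = "list", benignRadiance = "numeric",
                 injectedActivity = "numeric", referenceActivity = "numeric",
                 injectionTime = "POSIXct", isotope = "Isotope",
                 camera = "CameraModel", unfilteredBand = "OpticalBand",
                 filteredBand = "OpticalBand"),
  validity = function(object) {
    if (object@benignRadiance < 0) return("benignRadiance must be >= 0")
    if (object@injectedActivity <= 0) return("injectedActivity must be > 0")
    if (object@referenceActivity <= 0) return("referenceActivity must be > 0")
    for (l in object@lesions)
      if (!is(l, "LesionSpec")) return("lesions must be LesionSpec objects")
    TRUE
  }
)

#' A single CLI frame: photon counts plus acquisition metadata
#'
#' The unit every pipeline stage consumes and produces. Raw frames hold
#' non-negative integer photon counts within the camera bit depth; processed
#' frames (after smoothing) may hold non-negative reals. The processing
#' history is append-only provenance.
#'
#' @slot counts 2-D non-negative numeric raster (rows x cols)
#' @slot settings [AcquisitionSettings-class]
#' @slot acquisitionTime frame start timestamp (POSIXct)
#' @slot kind "specimen" or "background"
#' @slot view specimen view label, or "" for background frames
#' @slot history character vector of applied operations, append-only
#' @slot meta free-form list (simulator ground truth, seeds, strike counts)
#' @seealso [binPixels()], [suppressGammaStrikes()], [subtractBackground()]
#' @export
setClass("CLIFrame",
  representation(counts = "matrix", settings = "AcquisitionSettings",
                 acquisitionTime = "POSIXct", kind = "character",
                 view = "character", history = "character", meta = "list"),
  validity = function(object) {
    if (!is.numeric(object@counts)) return("counts must be numeric")
    if (any(!is.finite(object@counts))) return("counts must be finite")
    if (any(object@counts < 0)) return("counts must be >= 0")
    if (!object@kind %in% c("specimen", "background"))
      return("kind must be 'specimen' or 'background'")
    TRUE
  }
)

#' Calibrated radiance map (p/s/cm2/sr per pixel)
#'
#' @slot values 2-D non-negative real raster in p/s/cm2/sr
#' @slot settings [AcquisitionSettings-class] carried over from the frame
#' @slot acquisitionTime frame start timestamp (POSIXct)
#' @slot view specimen view label
#' @slot calibrationId label of the calibration used
#' @slot history processing provenance carried over from the frame
#' @seealso [countsToRadiance()], [roiMeanRadiance()]
#' @export
setClass("RadianceMap",
  representation(values = "matrix", settings = "AcquisitionSettings",
                 acquisitionTime = "POSIXct", view = "character",
                 calibrationId = "character", history = "character"),
  validity = function(object) {
    if (any(object@values < 0)) return("radiance values must be >= 0")
    TRUE
  }
)

#' Region of interest on the binned pixel grid
#'
#' @slot pixels integer matrix (n x 2) of (row, col) pixel coordinates
#' @slot label "tumour" or "background"
#' @slot view specimen view the ROI belongs to
#' @seealso [roi()], [roiFromMask()], [roiMeanRadiance()]
#' @export
setClass("ROI",
  representation(pixels = "matrix", label = "character", view = "character"),
  validity = function(object) {
    if (nrow(object@pixels) < 1L) return("ROI must contain at least one pixel")
    if (ncol(object@pixels) != 2L) return("pixels must be an n x 2 matrix")
    if (!object@label %in% c("tumour", "background"))
      return("label must be 'tumour' or 'background'")
    TRUE
  }
)

#' A detected hotspot on a specimen view
#'
#' A 4-connected component of pixels above the detection threshold,
#' annotated with its peak radiance, its TBR against the supplied background
#' on the unfiltered map, its TBR over the same pixels on the shortpass
#' filtered map (NA until matched), and the persistence flag.
#'
#' @slot view specimen view label
#' @slot pixels integer matrix (n x 2) of member pixels (binned grid)
#' @slot corePixels subset of `pixels` at or above half maximum (background
#'   subtracted); the compact ROI over which TBRs are measured
#' @slot peakRadiance maximum radiance inside the component
#' @slot tbrUnfiltered core mean / background mean on the unfiltered map
#' @slot tbrFiltered same-core TBR on the filtered map (NA if not matched)
#' @slot persistent TRUE when tbrFiltered >= tau_persist
#' @seealso [detectHotspots()], [matchFiltered()]
#' @export
setClass("Hotspot",
  representation(view = "character", pixels = "matrix",
                 corePixels = "matrix",
                 peakRadiance = "numeric", tbrUnfiltered = "numeric",
                 tbrFiltered = "numeric", persistent = "logical"),
  validity = function(object) {
    if (nrow(object@pixels) < 1L) return("hotspot must be non-empty")
    if (!is.na(object@tbrUnfiltered) && object@tbrUnfiltered <= 0)
      return("tbrUnfiltered must be > 0")
    TRUE
  }
)

#' Margin verdict for one specimen view
#'
#' Verdict is "PSM_suspected" exactly when at least one hotspot is
#' persistent on the shortpass-filtered image, "NSM" otherwise. The
#' rationale records which rule fired.
#'
#' @slot view specimen view label
#' @slot verdict "PSM_suspected" or "NSM"
#' @slot hotspots list of [Hotspot-class]
#' @slot rationale human-readable account of the decision
#' @seealso [classifyView()], [classifySpecimen()]
#' @export
setClass("MarginCall",
  representation(view = "character", verdict = "character",
                 hotspots = "list", rationale = "character"),
  validity = function(object) {
    if (!object@verdict %in% c("PSM_suspected", "NSM"))
      return("verdict must be 'PSM_suspected' or 'NSM'")
    pers <- vapply(object@hotspots,
                   function(h) isTRUE(h@persistent), logical(1))
    if ((object@verdict == "PSM_suspected") != any(pers))
      return("verdict must be PSM_suspected iff >= 1 persistent hotspot")
    TRUE
  }
)

#' A simulated or loaded specimen study
#'
#' Six-view CLI study: specimen frames, settings-matched background frames,
#' a manifest table, study metadata, and (for simulated studies) the ground
#' truth.
#'
#' @slot frames list of specimen [CLIFrame-class] objects
#' @slot backgrounds list of background [CLIFrame-class] objects, indexed by
#'   settings key
#' @slot manifest data.frame with one row per specimen frame (view, filter,
#'   exposure, binning, acquisitionTime, frame index, background key)
#' @slot patientId label
#' @slot injectedActivity MBq
#' @slot injectionTime POSIXct
#' @slot isotopeName isotope label
#' @slot groundTruth list: per-view labels, lesion masks and true TBRs
#'   (empty for real studies)
#' @seealso [renderStudy()], [writeStudy()], [readStudy()]
#' @export
setClass("SpecimenStudy",
  representation(frames = "list", backgrounds = "list",
                 manifest = "data.frame", patientId = "character",
                 injectedActivity = "numeric", injectionTime = "POSIXct",
                 isotopeName = "character", groundTruth = "list"),
  validity = function(object) {
    if (object@injectedActivity <= 0) return("injectedActivity must be > 0")
    if (nrow(object@manifest) != length(object@frames))
      return("manifest must have one row per specimen frame")
    TRUE
  }
)

.cliViews <- function() {
  c("left", "right", "anterior", "posterior", "basal", "apical")
}
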