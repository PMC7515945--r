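# Synthetic six-view specimen CLI study generator with ground truth.

#' Construct a camera model
#'
#' Defaults describe a plausible cooled photon-counting CLI camera: 117 um
#' unbinned pitch (so 2x2 binning gives the clinical 234 um), a 256 x 256
#' unbinned sensor, Gaussian read noise, a constant dark offset, sparse
#' exponential-amplitude gamma strikes, one fixed defective pixel rendered
#' at full scale, and a linear radiance-to-count conversion. None of these
#' reproduce a specific commercial device; they are declared configuration.
#'
#' @param pixelPitch unbinned pixel pitch (um)
#' @param sensorShape c(rows, cols) of the unbinned sensor
#' @param readNoiseSigma read noise sd (counts per unbinned pixel read)
#' @param darkOffset dark offset (counts per unbinned pixel)
#' @param gammaStrikeRate expected strikes per frame per second
#' @param gammaStrikeMean mean strike amplitude (counts); amplitudes are
#'   exponential, lower-truncated at 5x read noise
#' @param defectivePixels n x 2 integer matrix of (row, col); default one
#'   defective pixel
#' @param countsPerRadiance counts/s per unbinned pixel per unit radiance
#' @param bitDepth ADC bit depth (counts clip at 2^bitDepth - 1)
#' @return a [CameraModel-class]
#' @export
cameraModel <- function(pixelPitch = 117, sensorShape = c(256L, 256L),
                        readNoiseSigma = 2, darkOffset = 100,
                        gammaStrikeRate = 0.05, gammaStrikeMean = 500,
                        defectivePixels = matrix(c(40L, 200L), ncol = 2),
                        countsPerRadiance = 1e-4, bitDepth = 16L) {
  new("CameraModel", pixelPitch = pixelPitch,
      sensorShape = as.integer(sensorShape),
      readNoiseSigma = readNoiseSigma, darkOffset = darkOffset,
      gammaStrikeRate = gammaStrikeRate, gammaStrikeMean = gammaStrikeMean,
      defectivePixels = matrix(as.integer(defectivePixels), ncol = 2),
      countsPerRadiance = countsPerRadiance, bitDepth = as.integer(bitDepth))
}

#' Construct a lesion specification
#'
#' @param view specimen view the lesion appears on
#' @param center c(row, col) centre on the unbinned grid; default sensor
#'   centre is filled in by [phantomSpec()] when NULL
#' @param lateralSigma lateral Gaussian extent (mm)
#' @param depth depth below the excision surface (mm); 0 = tumour at the
#'   inked surface
#' @param ratio lesion:benign uptake ratio (true TBR)
#' @return a [LesionSpec-class]
#' @export
lesionSpec <- function(view, center = c(128, 128), lateralSigma = 2,
                       depth = 0, ratio = 8) {
  new("LesionSpec", view = view, center = as.numeric(center),
      lateralSigma = lateralSigma, depth = depth, ratio = ratio)
}

#' Construct a specimen phantom
#'
#' The phantom emulates an excised prostate specimen imaged on six sides:
#' a uniform benign surface radiance plus surface-proximal PSMA-avid
#' lesions, blurred laterally by lesion extent and positron range and
#' attenuated with depth according to the optical band. The benign radiance
#' default (500 p/s/cm2/sr at the 100 MBq reference) yields well-exposed
#' frames at the favoured clinical protocol (150 s, 8x8 binning).
#'
#' @param lesions list of [LesionSpec-class]; empty list for a
#'   lesion-free specimen
#' @param benignRadiance benign surface radiance (p/s/cm2/sr) at
#'   `referenceActivity`, referenced to injection time
#' @param injectedActivity injected activity (MBq)
#' @param referenceActivity normalization reference (MBq)
#' @param injectionTime injection timestamp (POSIXct)
#' @param isotope an [Isotope-class]
#' @param camera a [CameraModel-class]
#' @param unfilteredBand,filteredBand [OpticalBand-class] objects for the
#'   no-filter and shortpass acquisitions
#' @return a [PhantomSpec-class]
#' @examples
#' ph <- phantomSpec(lesions = list(lesionSpec("anterior", depth = 0)))
#' ph
#' @export
phantomSpec <- function(lesions = list(),
                        benignRadiance = 500,
                        injectedActivity = 100,
                        referenceActivity = 100,
                        injectionTime = as.POSIXct("2020-01-01 09:00:00",
                                                   tz = "UTC"),
                        isotope = getIsotope("Ga-68"),
                        camera = cameraModel(),
                        unfilteredBand = cliMargin::unfilteredBand(),
                        filteredBand = shortpassBand()) {
  new("PhantomSpec", lesions = lesions, benignRadiance = benignRadiance,
      injectedActivity = injectedActivity,
      referenceActivity = referenceActivity,
      injectionTime = injectionTime, isotope = isotope, camera = camera,
      unfilteredBand = unfilteredBand, filteredBand = filteredBand)
}

# positron-range blur: isotropic Gaussian whose mean radial displacement
# equals the isotope's mean range; for a 2-D Gaussian the mean radius is
# sigma * sqrt(pi/2), hence sigma = range / sqrt(pi/2)
.positronSigmaMM <- function(isotope) {
  isotope@meanPositronRange / sqrt(pi / 2)
}

.bandFor <- function(phantom, filter) {
  if (filter == "shortpass_550") phantom@filteredBand else phantom@unfilteredBand
}

# fraction of detectable Cerenkov light admitted by the filter (1/lambda^2
# spectral weight of the filtered band within the unfiltered band)
.filterThroughput <- function(phantom, filter) {
  if (filter == "shortpass_550")
    .bandPhotonWeight(phantom@filteredBand, phantom@unfilteredBand)
  else 1
}

#' Noise-free expected counts of a specimen view
#'
#' Analytic expectation of the photon counts of [renderView()] on the
#' unbinned grid, before read noise, gamma strikes and the defective pixel:
#' benign surface signal plus Gaussian lesion contributions (lateral extent
#' convolved with positron-range blur, attenuated by [tissueTransmission()]
#' at the lesion depth in the acquisition's band), scaled by decay since
#' injection, injected activity, filter throughput, exposure and the camera
#' calibration. Set `includeOffset = TRUE` to add the dark offset.
#'
#' @param phantom a [PhantomSpec-class]
#' @param view view label
#' @param settings an [AcquisitionSettings-class]
#' @param time acquisition start time (POSIXct), not before injection
#' @param includeOffset add the camera dark offset
#' @return numeric matrix of expected counts on the unbinned grid
#' @export
expectedCounts <- function(phantom, view, settings, time,
                           includeOffset = FALSE) {
  elapsed <- .minutesBetween(time, phantom@injectionTime)
  if (elapsed < 0) stop("acquisition before injection")
  cam <- phantom@camera
  nr <- cam@sensorShape[1]; nc <- cam@sensorShape[2]
  band <- .bandFor(phantom, settings@filter)
  base <- phantom@benignRadiance * cam@countsPerRadiance *
    (phantom@injectedActivity / phantom@referenceActivity) *
    decayFactor(elapsed, phantom@isotope@halfLife) *
    .filterThroughput(phantom, settings@filter) *
    settings@exposure
  mu <- matrix(base, nr, nc)
  pitchMM <- cam@pixelPitch / 1000
  for (l in phantom@lesions) {
    if (l@view != view) next
    sigmaPx <- sqrt(l@lateralSigma^2 + .positronSigmaMM(phantom@isotope)^2) /
      pitchMM
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    g <- exp(-((rows - l@center[1])^2 + (cols - l@center[2])^2) /
             (2 * sigmaPx^2))
    mu <- mu + base * (l@ratio - 1) * tissueTransmission(l@depth, band) * g
  }
  if (includeOffset) mu <- mu + cam@darkOffset
  mu
}

#' Ground-truth lesion mask on the binned grid
#'
#' Pixels whose lesion contribution is at least `threshold` of the lesion
#' peak, binned to the requested factor (a binned pixel is in the mask if
#' any member unbinned pixel is).
#'
#' @param phantom a [PhantomSpec-class]
#' @param lesion a [LesionSpec-class] belonging to the phantom
#' @param binning binning factor
#' @param threshold fraction of the peak (default 0.9, so the mask mean
#'   stays within a few percent of the peak contrast)
#' @return logical matrix on the binned grid
#' @export
lesionMask <- function(phantom, lesion, binning = 1L, threshold = 0.9) {
  cam <- phantom@camera
  nr <- cam@sensorShape[1]; nc <- cam@sensorShape[2]
  pitchMM <- cam@pixelPitch / 1000
  sigmaPx <- sqrt(lesion@lateralSigma^2 +
                  .positronSigmaMM(phantom@isotope)^2) / pitchMM
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  g <- exp(-((rows - lesion@center[1])^2 + (cols - lesion@center[2])^2) /
           (2 * sigmaPx^2))
  mask <- g >= threshold
  if (binning > 1L) {
    b <- as.integer(binning)
    nrb <- nr %/% b; ncb <- nc %/% b
    mask <- mask[seq_len(nrb * b), seq_len(ncb * b), drop = FALSE]
    dim(mask) <- c(b, nrb, b, ncb)
    mask <- apply(mask, c(2, 4), any)
  }
  mask
}

# read noise + dark offset + gamma strikes + defective pixels on an integer
# photon raster; returns list(counts, nStrikes)
.applyCameraArtifacts <- function(photons, cam, exposure) {
  nr <- nrow(photons); nc <- ncol(photons)
  x <- photons + cam@darkOffset +
    round(stats::rnorm(nr * nc, 0, cam@readNoiseSigma))
  nStrikes <- stats::rpois(1, cam@gammaStrikeRate * exposure)
  if (nStrikes > 0) {
    pos <- sample.int(nr * nc, nStrikes, replace = TRUE)
    amp <- 5 * cam@readNoiseSigma + stats::rexp(nStrikes, 1 / cam@gammaStrikeMean)
    for (i in seq_len(nStrikes)) x[pos[i]] <- x[pos[i]] + round(amp[i])
  }
  full <- 2^cam@bitDepth - 1
  if (nrow(cam@defectivePixels) > 0)
    x[cam@defectivePixels] <- full
  list(counts = pmax(x, 0), nStrikes = nStrikes)
}

.binAndClip <- function(x, b, bitDepth) {
  if (b > 1L) {
    nrb <- nrow(x) %/% b; ncb <- ncol(x) %/% b
    x <- x[seq_len(nrb * b), seq_len(ncb * b), drop = FALSE]
    dim(x) <- c(b, nrb, b, ncb)
    x <- colSums(colSums(aperm(x, c(1, 3, 2, 4))))
  }
  pmin(x, 2^bitDepth - 1)
}

#' Render one specimen view
#'
#' Draws a synthetic CLI frame: Poisson photon counts around the analytic
#' expectation of [expectedCounts()], then Gaussian read noise, dark
#' offset, gamma strikes, defective-pixel saturation, binning by summation
#' and clipping to the bit depth. Bit-identical for a fixed seed; the
#' caller's RNG stream is untouched. The number of injected gamma strikes
#' is recorded in the frame's meta.
#'
#' @inheritParams expectedCounts
#' @param seed integer seed
#' @return a specimen [CLIFrame-class] on the binned grid
#' @examples
#' ph <- phantomSpec(lesions = list(lesionSpec("anterior")))
#' st <- acquisitionSettings(150, 8, "shortpass_550")
#' renderView(ph, "anterior", st, as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
#'            seed = 1)
#' @export
renderView <- function(phantom, view, settings, time, seed) {
  mu <- expectedCounts(phantom, view, settings, time)
  cam <- phantom@camera
  res <- .withSeed(seed, {
    photons <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    .applyCameraArtifacts(photons, cam, settings@exposure)
  })
  b <- settings@binning
  countsB <- .binAndClip(res$counts, b, cam@bitDepth)
  st <- acquisitionSettings(settings@exposure, b, settings@filter,
                            unbinnedPitch = cam@pixelPitch)
  new("CLIFrame", counts = countsB, settings = st, acquisitionTime = time,
      kind = "specimen", view = view, history = "acquired",
      meta = list(seed = seed, nStrikes = res$nStrikes))
}

#' Render an empty-tray background frame
#'
#' Frame with zero specimen signal: dark offset, read noise, gamma strikes
#' and the defective pixel only, binned and clipped like a specimen frame.
#'
#' @inheritParams renderView
#' @param time acquisition timestamp (defaults to the injection time; a
#'   background carries no decaying signal)
#' @return a background [CLIFrame-class]
#' @export
renderBackground <- function(phantom, settings, seed,
                             time = phantom@injectionTime) {
  cam <- phantom@camera
  zero <- matrix(0, cam@sensorShape[1], cam@sensorShape[2])
  res <- .withSeed(seed, .applyCameraArtifacts(zero, cam, settings@exposure))
  countsB <- .binAndClip(res$counts, settings@binning, cam@bitDepth)
  st <- acquisitionSettings(settings@exposure, settings@binning,
                            settings@filter, unbinnedPitch = cam@pixelPitch)
  new("CLIFrame", counts = countsB, settings = st, acquisitionTime = time,
      kind = "background", view = "", history = "acquired",
      meta = list(seed = seed, nStrikes = res$nStrikes))
}

.settingsKey <- function(settings) {
  sprintf("%gs_b%d_%s", settings@exposure, settings@binning, settings@filter)
}

.truthLabel <- function(depths, closeBand = 0.1) {
  if (length(depths) == 0) return("NSM")
  if (any(depths == 0)) return("PSM")
  if (any(depths < closeBand)) return("CLOSE")
  "NSM"
}

#' Render a complete six-view study with ground truth
#'
#' Acquires every view with every protocol setting, with frame start times
#' advancing by the exposure time, plus one settings-matched empty-tray
#' background per unique setting. Per-frame seeds are derived
#' deterministically from the master seed, so studies are reproducible
#' frame-by-frame. The ground truth records the per-view margin label
#' ("PSM" for any lesion at depth 0, "CLOSE" for depths below 0.1 mm,
#' "NSM" otherwise), each lesion's true TBR and its mask on the binned grid
#' of each protocol setting.
#'
#' @param phantom a [PhantomSpec-class]
#' @param protocol non-empty list of [AcquisitionSettings-class]
#' @param startTime acquisition start of the first frame; must not precede
#'   injection
#' @param seed master integer seed
#' @param views views to acquire (all six by default)
#' @param patientId label stored in the study
#' @return a [SpecimenStudy-class]; `groundTruth(study)` holds the labels
#' @examples
#' ph <- phantomSpec(lesions = list(lesionSpec("anterior", depth = 0)))
#' prot <- list(acquisitionSettings(150, 8, "none"),
#'              acquisitionSettings(150, 8, "shortpass_550"))
#' st <- renderStudy(ph, prot,
#'                   as.POSIXct("2020-01-01 10:00:00", tz = "UTC"), seed = 1)
#' groundTruth(st)$labels
#' @export
renderStudy <- function(phantom, protocol, startTime, seed,
                        views = .cliViews(), patientId = "synthetic") {
  if (length(protocol) == 0) stop("protocol must be non-empty")
  nFrames <- length(views) * length(protocol)
  keys <- unique(vapply(protocol, .settingsKey, character(1)))
  seeds <- .deriveSeeds(seed, nFrames + length(keys))
  frames <- vector("list", nFrames)
  manifest <- data.frame(index = integer(), view = character(),
                         exposure = numeric(), binning = integer(),
                         filter = character(), acquisitionTime = character(),
                         seed = integer(), backgroundKey = character(),
                         stringsAsFactors = FALSE)
  t <- startTime
  i <- 0L
  for (v in views) {
    for (st in protocol) {
      i <- i + 1L
      frames[[i]] <- renderView(phantom, v, st, t, seeds[i])
      manifest <- rbind(manifest, data.frame(
        index = i, view = v, exposure = st@exposure, binning = st@binning,
        filter = st@filter,
        acquisitionTime = format(t, "%Y-%m-%dT%H:%M:%S%z"),
        seed = seeds[i], backgroundKey = .settingsKey(st),
        stringsAsFactors = FALSE))
      t <- t + st@exposure
    }
  }
  backgrounds <- list()
  uprot <- protocol[!duplicated(vapply(protocol, .settingsKey, character(1)))]
  for (j in seq_along(uprot)) {
    key <- .settingsKey(uprot[[j]])
    backgrounds[[key]] <- renderBackground(phantom, uprot[[j]],
                                           seeds[nFrames + j])
  }
  labels <- vapply(views, function(v) {
    d <- vapply(Filter(function(l) l@view == v, phantom@lesions),
                function(l) l@depth, numeric(1))
    .truthLabel(d)
  }, character(1))
  lesionTruth <- lapply(phantom@lesions, function(l) {
    masks <- lapply(unique(vapply(protocol, function(s) s@binning,
                                  integer(1))),
                    function(b) lesionMask(phantom, l, b))
    names(masks) <- as.character(
      unique(vapply(protocol, function(s) s@binning, integer(1))))
    list(view = l@view, depth = l@depth, trueTBR = l@ratio, masks = masks)
  })
  new("SpecimenStudy", frames = frames, backgrounds = backgrounds,
      manifest = manifest, patientId = patientId,
      injectedActivity = phantom@injectedActivity,
      injectionTime = phantom@injectionTime,
      isotopeName = phantom@isotope@name,
      groundTruth = list(labels = labels, lesions = lesionTruth,
                         totalMinutes = .minutesBetween(t, startTime)))
}
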