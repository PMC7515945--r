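# Study persistence: 16-bit TIFF frames with JSON sidecars, YAML manifest,
# JSON ground truth, CSV reports. Counts are stored bit-exactly; radiance
# maps are stored as 32-bit float TIFF normalized by a scale factor
# recorded in the sidecar (the TIFF writer stores [0,1] faithfully).

.parseTime <- function(x) {
  x <- sub("Z$", "+0000", x)
  for (fmt in c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S")) {
    t <- as.POSIXct(x, format = fmt, tz = "UTC")
    if (!is.na(t)) return(t)
  }
  stop("unparseable timestamp: ", x)
}

.formatTime <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z")

.writeFrameTiff <- function(frame, path) {
  full <- 65535
  tiff::writeTIFF(frame@counts / full, path, bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(kind = frame@kind, view = frame@view,
                  exposure_s = frame@settings@exposure,
                  binning = frame@settings@binning,
                  filter = frame@settings@filter,
                  pixel_pitch_um = frame@settings@pixelPitch,
                  acquisition_time = .formatTime(frame@acquisitionTime),
                  history = as.list(frame@history),
                  seed = frame@meta$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.readFrameTiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  st <- new("AcquisitionSettings", exposure = sc$exposure_s,
            binning = as.integer(sc$binning), filter = sc$filter,
            pixelPitch = sc$pixel_pitch_um)
  new("CLIFrame", counts = matrix(as.numeric(m), nrow(m), ncol(m)),
      settings = st, acquisitionTime = .parseTime(sc$acquisition_time),
      kind = sc$kind, view = if (is.null(sc$view)) "" else sc$view,
      history = as.character(unlist(sc$history)),
      meta = if (is.null(sc$seed)) list() else list(seed = sc$seed))
}

#' Write a study to disk
#'
#' Writes every specimen frame and background as a bit-exact 16-bit TIFF
#' with a JSON sidecar (settings, timestamp, seed, history), a YAML study
#' manifest, and the ground truth (labels and lesion geometry) as JSON.
#'
#' @param study a [SpecimenStudy-class]
#' @param dir output directory (created if missing)
#' @return the manifest path, invisibly
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- study@manifest
  framePaths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    framePaths[i] <- sprintf("frame_%03d_%s_%s.tif", m$index[i], m$view[i],
                             m$backgroundKey[i])
    .writeFrameTiff(study@frames[[i]], file.path(dir, framePaths[i]))
  }
  bgPaths <- character(length(study@backgrounds))
  names(bgPaths) <- names(study@backgrounds)
  for (key in names(study@backgrounds)) {
    bgPaths[key] <- sprintf("background_%s.tif", key)
    .writeFrameTiff(study@backgrounds[[key]], file.path(dir, bgPaths[key]))
  }
  manifest <- list(
    patient_id = study@patientId,
    isotope = study@isotopeName,
    injected_activity_MBq = study@injectedActivity,
    injection_time = .formatTime(study@injectionTime),
    frames = lapply(seq_len(nrow(m)), function(i) list(
      path = framePaths[i], view = m$view[i], kind = "specimen",
      exposure_s = m$exposure[i], binning = m$binning[i],
      filter = m$filter[i], acquisition_time = m$acquisitionTime[i],
      seed = m$seed[i], background = unname(bgPaths[m$backgroundKey[i]]))),
    backgrounds = lapply(names(bgPaths), function(k) list(
      key = k, path = unname(bgPaths[k]))))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (length(study@groundTruth)) {
    gt <- study@groundTruth
    pick <- function(l, a, b) if (!is.null(l[[a]])) l[[a]] else l[[b]]
    jsonlite::write_json(
      list(labels = as.list(gt$labels),
           total_minutes = gt$totalMinutes,
           lesions = lapply(gt$lesions, function(l)
             list(view = l$view, depth_mm = pick(l, "depth", "depth_mm"),
                  true_tbr = pick(l, "trueTBR", "true_tbr")))),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file.path(dir, "manifest.yaml"))
}

#' Read a study from disk
#'
#' Loads a study written by [writeStudy()] (or assembled by hand in the
#' same layout). Every frame path in the manifest must exist.
#'
#' @param dir study directory containing manifest.yaml
#' @return a [SpecimenStudy-class]
#' @export
readStudy <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  frames <- list(); rows <- list()
  bgByPath <- list()
  backgrounds <- list()
  for (b in mf$backgrounds) {
    fr <- .readFrameTiff(file.path(dir, b$path))
    backgrounds[[b$key]] <- fr
    bgByPath[[b$path]] <- b$key
  }
  for (i in seq_along(mf$frames)) {
    f <- mf$frames[[i]]
    p <- file.path(dir, f$path)
    if (!file.exists(p)) stop("frame path missing: ", f$path)
    frames[[i]] <- .readFrameTiff(p)
    rows[[i]] <- data.frame(index = i, view = f$view,
                            exposure = f$exposure_s,
                            binning = as.integer(f$binning),
                            filter = f$filter,
                            acquisitionTime = f$acquisition_time,
                            seed = if (is.null(f$seed)) NA_integer_ else f$seed,
                            backgroundKey = bgByPath[[f$background]],
                            stringsAsFactors = FALSE)
  }
  gtPath <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtPath)) {
    raw <- jsonlite::read_json(gtPath, simplifyVector = FALSE)
    list(labels = unlist(raw$labels), lesions = raw$lesions,
         totalMinutes = raw$total_minutes)
  } else list()
  new("SpecimenStudy", frames = frames, backgrounds = backgrounds,
      manifest = do.call(rbind, rows), patientId = mf$patient_id,
      injectedActivity = mf$injected_activity_MBq,
      injectionTime = .parseTime(mf$injection_time),
      isotopeName = mf$isotope, groundTruth = gt)
}

.knownConfigKeys <- c("patient_id", "isotope", "injected_activity_MBq",
                      "injection_time", "benign_radiance",
                      "reference_activity_MBq", "acquisition_delay_min",
                      "lesions", "protocol", "camera")
.knownLesionKeys <- c("view", "depth_mm", "ratio", "lateral_sigma_mm",
                      "center")
.knownProtocolKeys <- c("exposure_s", "binning", "filter")

#' Read a phantom/study configuration
#'
#' Parses a versioned YAML study configuration into a phantom, protocol and
#' start time. Unknown keys are errors (fail-fast).
#'
#' @param path YAML config path; see `system.file("extdata",
#'   "default_study.yaml", package = "cliMargin")` for the schema
#' @return list(phantom, protocol, startTime, patientId)
#' @export
readStudyConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .knownConfigKeys)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  lesions <- lapply(cfg$lesions, function(l) {
    badl <- setdiff(names(l), .knownLesionKeys)
    if (length(badl)) stop("unknown lesion keys: ",
                           paste(badl, collapse = ", "))
    lesionSpec(l$view,
               center = if (is.null(l$center)) c(128, 128)
                        else as.numeric(unlist(l$center)),
               lateralSigma = if (is.null(l$lateral_sigma_mm)) 2
                              else l$lateral_sigma_mm,
               depth = if (is.null(l$depth_mm)) 0 else l$depth_mm,
               ratio = if (is.null(l$ratio)) 5 else l$ratio)
  })
  protocol <- lapply(cfg$protocol, function(p) {
    badp <- setdiff(names(p), .knownProtocolKeys)
    if (length(badp)) stop("unknown protocol keys: ",
                           paste(badp, collapse = ", "))
    acquisitionSettings(p$exposure_s, p$binning,
                        if (is.null(p$filter)) "none" else p$filter)
  })
  injTime <- .parseTime(cfg$injection_time)
  ph <- phantomSpec(
    lesions = lesions,
    benignRadiance = if (is.null(cfg$benign_radiance)) 500
                     else cfg$benign_radiance,
    injectedActivity = cfg$injected_activity_MBq,
    referenceActivity = if (is.null(cfg$reference_activity_MBq)) 100
                        else cfg$reference_activity_MBq,
    injectionTime = injTime,
    isotope = getIsotope(if (is.null(cfg$isotope)) "Ga-68" else cfg$isotope))
  delay <- if (is.null(cfg$acquisition_delay_min)) 73
           else cfg$acquisition_delay_min
  list(phantom = ph, protocol = protocol,
       startTime = injTime + delay * 60,
       patientId = if (is.null(cfg$patient_id)) "synthetic"
                   else cfg$patient_id)
}

#' Simulate a study from a configuration file
#'
#' Renders the study described by a YAML configuration and writes frames,
#' sidecars, manifest and ground truth to `outputDir`; bit-identical for a
#' fixed seed.
#'
#' @param configPath YAML configuration (see [readStudyConfig()])
#' @param outputDir output directory
#' @param seed master seed
#' @return the written [SpecimenStudy-class], invisibly
#' @export
simulateStudy <- function(configPath, outputDir, seed) {
  cfg <- readStudyConfig(configPath)
  study <- renderStudy(cfg$phantom, cfg$protocol, cfg$startTime, seed,
                       patientId = cfg$patientId)
  writeStudy(study, outputDir)
  invisible(study)
}

#' Process every specimen frame of a study
#'
#' Runs the standard chain (gamma-strike suppression, settings-matched
#' background subtraction, radiance calibration) over every specimen frame.
#' A frame without a settings-matched background is a hard error naming the
#' frame, mirroring the acquisition requirement that backgrounds share the
#' specimen frame's settings.
#'
#' @param study a [SpecimenStudy-class]
#' @param calibration counts per (p/s/cm2/sr) s pixel
#' @return list of [RadianceMap-class], one per manifest row
#' @export
processStudy <- function(study, calibration = 1) {
  m <- study@manifest
  lapply(seq_len(nrow(m)), function(i) {
    bg <- study@backgrounds[[m$backgroundKey[i]]]
    if (is.null(bg))
      stop("no settings-matched background for frame ", m$index[i],
           " (view ", m$view[i], ", ", m$backgroundKey[i], ")")
    processFrame(study@frames[[i]], bg, calibration = calibration)
  })
}

#' Write radiance maps as scaled 32-bit float TIFFs
#'
#' @param maps list of [RadianceMap-class] from [processStudy()]
#' @param dir output directory
#' @return written paths, invisibly
#' @export
writeRadianceMaps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(maps))
  for (i in seq_along(maps)) {
    mp <- maps[[i]]
    scale <- max(mp@values, 1e-12)
    paths[i] <- file.path(dir, sprintf("radiance_%03d_%s_%s.tif", i,
                                       mp@view, mp@settings@filter))
    tiff::writeTIFF(mp@values / scale, paths[i], bits.per.sample = 32L,
                    compression = "none")
    jsonlite::write_json(
      list(scale = scale, view = mp@view, filter = mp@settings@filter,
           exposure_s = mp@settings@exposure,
           binning = mp@settings@binning,
           acquisition_time = .formatTime(mp@acquisitionTime),
           calibration_id = mp@calibrationId,
           history = as.list(mp@history)),
      paste0(paths[i], ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Quantification and margin report for a study
#'
#' Processes the study, quantifies every specimen frame (background ROI
#' statistics, strongest-hotspot radiance with decay and activity
#' correction, TBR) and applies the persistence rule per view using the
#' unfiltered/filtered pair at the highest shared exposure. Returns the
#' per-frame table, per-view margin calls and the specimen-level verdict.
#'
#' @param study a [SpecimenStudy-class]
#' @param calibration counts per (p/s/cm2/sr) s pixel
#' @param halfLife isotope half-life (minutes); defaults to the registry
#'   value for the study's isotope
#' @param referenceActivity activity normalization reference (MBq)
#' @param kSigma,minArea,tauPersist classifier parameters, see
#'   [classifyView()]
#' @return list: `frames` data.frame, `calls` list of [MarginCall-class],
#'   `specimenVerdict`
#' @export
reportStudy <- function(study, calibration = 1, halfLife = NULL,
                        referenceActivity = 100, kSigma = 3, minArea = 4L,
                        tauPersist = 2) {
  if (is.null(halfLife))
    halfLife <- getIsotope(study@isotopeName)@halfLife
  maps <- processStudy(study, calibration)
  m <- study@manifest
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    mp <- maps[[i]]
    bg <- backgroundStats(mp)
    hs <- detectHotspots(mp, bg, kSigma = kSigma, minArea = minArea)
    hot <- if (length(hs)) {
      best <- hs[[which.max(vapply(hs, function(h) h@tbrUnfiltered,
                                   numeric(1)))]]
      mean(mp@values[best@corePixels])
    } else NA_real_
    dc <- if (is.na(hot)) NA_real_ else
      decayCorrect(hot, mp@acquisitionTime, study@injectionTime, halfLife)
    ac <- if (is.na(hot)) NA_real_ else
      activityNormalize(dc, study@injectedActivity, referenceActivity)
    rows[[i]] <- data.frame(
      index = i, view = m$view[i], filter = m$filter[i],
      exposure = m$exposure[i], binning = m$binning[i],
      backgroundRadiance = bg[["mean"]], hotspotRadiance = hot,
      hotspotDecayCorrected = dc, hotspotActivityCorrected = ac,
      tbr = if (is.na(hot)) NA_real_ else hot / bg[["mean"]],
      nHotspots = length(hs), stringsAsFactors = FALSE)
  }
  frames <- do.call(rbind, rows)
  calls <- list()
  for (v in unique(m$view)) {
    iU <- which(m$view == v & m$filter == "none")
    iF <- which(m$view == v & m$filter == "shortpass_550")
    if (length(iU) == 0) next
    iU <- iU[which.max(m$exposure[iU])]
    match <- iF[m$exposure[iF] == m$exposure[iU] &
                m$binning[iF] == m$binning[iU]]
    fMap <- if (length(match)) maps[[match[1]]] else NULL
    calls[[v]] <- classifyView(maps[[iU]], fMap, kSigma = kSigma,
                               minArea = minArea, tauPersist = tauPersist)
  }
  list(frames = frames, calls = calls,
       specimenVerdict = if (length(calls)) classifySpecimen(calls)
                         else NA_character_)
}

#' Write a study report as CSV
#'
#' RFC 4180 CSV with radiances to 4 significant figures and TBR to one
#' decimal (the clinical table convention), followed by one margin-call
#' row per view.
#'
#' @param report list from [reportStudy()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeStudyReport <- function(report, path) {
  df <- report$frames
  for (col in c("backgroundRadiance", "hotspotRadiance",
                "hotspotDecayCorrected", "hotspotActivityCorrected"))
    df[[col]] <- signif(df[[col]], 4)
  df$tbr <- round(df$tbr, 1)
  df$viewVerdict <- vapply(df$view, function(v)
    if (!is.null(report$calls[[v]])) verdict(report$calls[[v]])
    else NA_character_, character(1))
  df$specimenVerdict <- report$specimenVerdict
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
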