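test_that("lesion-free noise-free phantom has a uniform analytic expectation", {
  ph <- phantomSpec(lesions = list(), camera = quietCamera())
  st <- acquisitionSettings(150, 1, "none")
  t0 <- injTime + 68 * 60
  mu <- expectedCounts(ph, "anterior", st, t0)
  # benign 500 p/s/cm2/sr * 1e-4 counts/s per radiance * 0.5 decay * 150 s
  expect_equal(unique(as.vector(mu)), 500 * 1e-4 * 0.5 * 150,
               tolerance = 1e-12)
  expect_equal(dim(mu), c(256L, 256L))
})

test_that("rendering is bit-identical under a fixed seed", {
  ph <- phantomSpec(lesions = list(lesionSpec("anterior")))
  st <- acquisitionSettings(150, 8, "none")
  t0 <- injTime + 60 * 60
  a <- renderView(ph, "anterior", st, t0, seed = 99)
  b <- renderView(ph, "anterior", st, t0, seed = 99)
  expect_identical(counts(a), counts(b))
  c <- renderView(ph, "anterior", st, t0, seed = 100)
  expect_false(identical(counts(a), counts(c)))
})

test_that("acquisition before injection is rejected", {
  ph <- phantomSpec()
  st <- acquisitionSettings(150, 8, "none")
  expect_error(renderView(ph, "anterior", st, injTime - 60, seed = 1),
               "before injection")
})

test_that("depth attenuates the filtered hotspot more than the unfiltered", {
  t0 <- injTime + 60 * 60
  stU <- acquisitionSettings(150, 1, "none")
  stF <- acquisitionSettings(150, 1, "shortpass_550")
  contrast <- function(depth, st) {
    ph <- phantomSpec(lesions = list(lesionSpec("anterior", depth = depth)))
    mu <- expectedCounts(ph, "anterior", st, t0)
    base <- min(mu)
    (max(mu) - base) / base
  }
  # deep lesion: filtered contrast well below unfiltered
  expect_lt(contrast(6, stF), contrast(6, stU))
  # surface lesion: the two contrasts agree within 10%
  expect_equal(contrast(0, stF) / contrast(0, stU), 1, tolerance = 0.1)
})

test_that("background frames carry offset, defective pixel and CLT mean", {
  # noise-free camera: constant dark offset
  ph0 <- phantomSpec(camera = cameraModel(
    readNoiseSigma = 0, darkOffset = 100, gammaStrikeRate = 0,
    defectivePixels = matrix(integer(0), ncol = 2)))
  st <- acquisitionSettings(150, 1, "none")
  bg0 <- renderBackground(ph0, st, seed = 1)
  expect_true(all(counts(bg0) == 100))
  # defective pixel at saturation on every frame
  phD <- phantomSpec(camera = cameraModel(gammaStrikeRate = 0))
  bgD <- renderBackground(phD, st, seed = 2)
  expect_identical(counts(bgD)[40, 200], 65535)
  # mean of 100 seeded backgrounds near the dark offset (CLT)
  phC <- phantomSpec(camera = cameraModel(
    sensorShape = c(24L, 24L), readNoiseSigma = 2, darkOffset = 100,
    gammaStrikeRate = 0, defectivePixels = matrix(integer(0), ncol = 2)))
  acc <- 0
  for (s in 1:100) acc <- acc + mean(counts(renderBackground(phC, st, s)))
  expect_lt(abs(acc / 100 - 100), 3 * 2 / 10)
})

test_that("pixel means converge to the analytic expectation", {
  ph <- phantomSpec(
    benignRadiance = 15000,   # ~112 counts/pixel at one half-life, 100 s
    camera = cameraModel(sensorShape = c(8L, 8L), readNoiseSigma = 2,
                         darkOffset = 50, gammaStrikeRate = 0,
                         defectivePixels = matrix(integer(0), ncol = 2)))
  st <- acquisitionSettings(100, 1, "none")
  t0 <- injTime + 68 * 60
  mu <- expectedCounts(ph, "left", st, t0, includeOffset = TRUE)
  expect_gt(mu[1, 1], 100)
  n <- 4000
  acc <- matrix(0, 8, 8)
  for (s in seq_len(n)) acc <- acc + counts(renderView(ph, "left", st, t0, s))
  expect_equal(mean(acc / n) / mean(mu), 1, tolerance = 0.01)
})

test_that("expected signal halves after one half-life", {
  ph <- phantomSpec(lesions = list(lesionSpec("anterior", depth = 1)))
  st <- acquisitionSettings(150, 1, "none")
  t0 <- injTime + 30 * 60
  mu1 <- expectedCounts(ph, "anterior", st, t0)
  mu2 <- expectedCounts(ph, "anterior", st, t0 + 68 * 60)
  expect_equal(mu2, mu1 / 2, tolerance = 1e-12)
})

test_that("gamma-strike counts per frame are Poisson(rate x exposure)", {
  ph <- phantomSpec(camera = cameraModel(
    sensorShape = c(16L, 16L), gammaStrikeRate = 0.05,
    defectivePixels = matrix(integer(0), ncol = 2)))
  st <- acquisitionSettings(150, 1, "none")
  nFrames <- 500
  ks <- vapply(seq_len(nFrames), function(s)
    frameMeta(renderBackground(ph, st, s))$nStrikes, numeric(1))
  lambda <- 0.05 * 150
  # pool Poisson bins so every expected count is >= 5
  breaks <- c(-Inf, 3:12, Inf)
  obs <- table(cut(ks, breaks))
  pr <- diff(ppois(c(-Inf, 3:12, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("a full study has the right frames, timing and truth labels", {
  ph <- phantomSpec(lesions = list(
    lesionSpec("anterior", depth = 0),
    lesionSpec("left", depth = 0.05),
    lesionSpec("right", depth = 4)))
  prot <- list(acquisitionSettings(150, 8, "none"),
               acquisitionSettings(150, 8, "shortpass_550"))
  t0 <- injTime + 73 * 60
  study <- renderStudy(ph, prot, t0, seed = 3)
  expect_length(study@frames, 12)
  expect_length(study@backgrounds, 2)
  expect_equal(nrow(studyManifest(study)), 12)
  gt <- groundTruth(study)
  expect_lte(gt$totalMinutes, 45)
  expect_identical(unname(gt$labels["anterior"]), "PSM")
  expect_identical(unname(gt$labels["left"]), "CLOSE")
  expect_identical(unname(gt$labels["right"]), "NSM")
  expect_identical(unname(gt$labels["basal"]), "NSM")
  # matched background exists for every frame's settings key
  expect_true(all(studyManifest(study)$backgroundKey %in%
                  names(study@backgrounds)))
  expect_error(renderStudy(ph, list(), t0, seed = 1), "non-empty")
})
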