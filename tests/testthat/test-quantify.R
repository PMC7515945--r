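test_that("ROI mean radiance: uniform, arithmetic, brute-force oracle, bounds", {
  u <- makeMap(matrix(3.7, 8, 8))
  anyRoi <- roi(cbind(c(2L, 3L, 5L), c(2L, 7L, 4L)))
  expect_equal(roiMeanRadiance(u, anyRoi), 3.7)
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 1] <- 2; m[1, 2] <- 3; m[2, 2] <- 4
  four <- roi(cbind(c(1L, 2L, 1L, 2L), c(1L, 1L, 2L, 2L)))
  expect_equal(roiMeanRadiance(makeMap(m), four), 2.5)
  set.seed(23)
  big <- matrix(runif(32 * 32), 32, 32)
  px <- cbind(sample(32, 100, TRUE), sample(32, 100, TRUE))
  got <- roiMeanRadiance(makeMap(big), roi(px))
  want <- 0
  for (i in 1:100) want <- want + big[px[i, 1], px[i, 2]]
  expect_equal(got, want / 100, tolerance = 1e-12)
  expect_error(roi(matrix(integer(0), ncol = 2)), "at least one")
  expect_error(roiMeanRadiance(u, roi(cbind(9L, 1L))), "bounds")
})

test_that("decay correction doubles after one half-life and inverts decay", {
  expect_equal(decayCorrect(100, injTime, injTime, 68), 100)
  expect_equal(decayCorrect(100, injTime + 68 * 60, injTime, 68), 200)
  set.seed(31)
  for (i in 1:20) {
    t <- round(runif(1, 0, 300) * 60) / 60   # whole seconds: exact POSIXct
    r <- runif(1, 1, 1e4)
    expect_equal(decayCorrect(decayFactor(t, 68) * r, injTime + t * 60,
                              injTime, 68), r, tolerance = 1e-12)
  }
  expect_error(decayCorrect(1, injTime - 60, injTime, 68), "before injection")
})

test_that("activity normalization scales and inverts correctly", {
  expect_equal(activityNormalize(10, 100, 100), 10)
  expect_equal(activityNormalize(10, 50, 100), 20)
  expect_equal(activityNormalize(activityNormalize(7, 83, 100), 100, 83), 7)
  expect_error(activityNormalize(1, 0), "activities")
})

test_that("TBR: unit, ratio, common-scale invariance, zero background", {
  expect_equal(tbr(2, 2), 1)
  expect_equal(tbr(4, 2), 2)
  set.seed(37)
  for (i in 1:20) {
    s <- runif(1, 0.01, 100); t <- runif(1, 1, 10); b <- runif(1, 0.1, 5)
    expect_equal(tbr(s * t, s * b), tbr(t, b), tolerance = 1e-12)
  }
  expect_error(tbr(1, 0), "background")
})

test_that("TBR rejects measurements from different frames", {
  vals <- matrix(2, 4, 4); vals[1, 1] <- 4
  mapA <- makeMap(vals, view = "left")
  mapB <- makeMap(matrix(2, 4, 4), view = "right")
  t <- measureROI(mapA, roi(cbind(1L, 1L), view = "left"), injTime)
  b <- measureROI(mapB, roi(cbind(1L, 1L), label = "background",
                            view = "right"), injTime)
  expect_error(tbr(t, b), "same frame")
  bSame <- measureROI(mapA, roi(cbind(2L, 2L), label = "background",
                                view = "left"), injTime)
  expect_equal(tbr(t, bSame), 2)
})

test_that("cohort summary uses the population-sd convention", {
  act <- cohortSummary(c(118, 68, 88, 76, 65))
  expect_identical(round(act[["mean"]]), 83)
  expect_identical(round(act[["sd"]]), 19)
  filt <- cohortSummary(c(3.1, 2.2, 3.1, 5.9))
  expect_identical(round(filt[["mean"]], 1), 3.6)
  expect_identical(round(filt[["sd"]], 1), 1.4)
  nofilt <- cohortSummary(c(1.8, 2.6, 1.8))
  expect_identical(round(nofilt[["mean"]], 1), 2.1)
  expect_identical(round(nofilt[["sd"]], 1), 0.4)
  expect_equal(cohortSummary(5), c(mean = 5, sd = 0))
  # sample flag gives the n-1 convention instead
  expect_equal(cohortSummary(c(1, 2, 3), sample = TRUE)[["sd"]], 1)
  expect_error(cohortSummary(numeric(0)), "empty")
})

test_that("cohort mean is translation-equivariant, sd translation-invariant", {
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(7, 50, 10); c <- runif(1, -20, 20)
    a <- cohortSummary(x); b <- cohortSummary(x + c)
    expect_equal(b[["mean"]], a[["mean"]] + c, tolerance = 1e-12)
    expect_equal(b[["sd"]], a[["sd"]], tolerance = 1e-12)
  }
})

test_that("measured TBR recovers the configured uptake ratio within 10%", {
  # surface lesion, unfiltered, low noise: quantification chain without
  # smoothing (no strikes to suppress on a quiet camera)
  t0 <- injTime + 73 * 60
  st <- acquisitionSettings(150, 2, "none")
  ratios <- numeric(20)
  for (s in 1:20) {
    ph <- phantomSpec(
      lesions = list(lesionSpec("anterior", depth = 0, ratio = 8)),
      benignRadiance = 5000,
      camera = quietCamera())
    fr <- renderView(ph, "anterior", st, t0, seed = 1000 + s)
    bg <- renderBackground(ph, st, seed = 2000 + s)
    map <- countsToRadiance(subtractBackground(fr, bg))
    tumourROI <- roiFromMask(lesionMask(ph, ph@lesions[[1]], 2))
    bgStats <- backgroundStats(map)
    ratios[s] <- roiMeanRadiance(map, tumourROI) / bgStats[["mean"]]
  }
  expect_equal(mean(ratios), 8, tolerance = 0.1)
  expect_true(all(abs(ratios - 8) / 8 < 0.1))
})
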