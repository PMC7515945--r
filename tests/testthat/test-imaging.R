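test_that("binning: identity, conservation, brute-force oracle, cropping", {
  f1 <- makeFrame(matrix(1, 4, 4))
  expect_identical(counts(binPixels(f1, 1)), counts(f1))
  b2 <- binPixels(f1, 2)
  expect_true(all(counts(b2) == 4))
  expect_equal(sum(counts(b2)), sum(counts(f1)))
  expect_equal(binningFactor(b2), 2L)
  set.seed(7)
  m <- matrix(rpois(256, 40), 16, 16)
  expect_equal(counts(binPixels(makeFrame(m), 8)), oracleBinSum(m, 8))
  expect_equal(counts(binPixels(makeFrame(m), 4)), oracleBinSum(m, 4))
  # non-divisible dimensions: trailing rows/cols cropped, never padded
  m5 <- matrix(seq_len(25), 5, 5)
  expect_equal(counts(binPixels(makeFrame(m5), 2)),
               oracleBinSum(m5[1:4, 1:4], 2))
  expect_error(binPixels(makeFrame(m5), 0), "factor")
})

test_that("strike suppression: constants fixed, impulses killed, oracle match", {
  const <- makeFrame(matrix(17, 12, 12))
  expect_equal(counts(suppressGammaStrikes(const)), matrix(17, 12, 12),
               tolerance = 1e-12)
  # isolated impulse on a flat field vanishes to < 1% of its amplitude
  imp <- matrix(50, 21, 21); imp[11, 11] <- imp[11, 11] + 1e4
  out <- counts(suppressGammaStrikes(makeFrame(imp)))
  expect_true(all(abs(out - 50) < 0.01 * 1e4))
  # arbitrary raster equals the direct median-then-Gaussian oracle
  set.seed(11)
  m <- matrix(rpois(20 * 24, 30) + runif(480), 20, 24)
  got <- counts(suppressGammaStrikes(makeFrame(m), 3, 3))
  want <- oracleGauss(oracleMedian(m, 3), 3)
  expect_equal(got, want, tolerance = 1e-6)
  # configurable order
  gotG <- counts(suppressGammaStrikes(makeFrame(m), 3, 3,
                                      order = "gaussian_first"))
  expect_equal(gotG, oracleMedian(oracleGauss(m, 3), 3), tolerance = 1e-6)
  expect_error(suppressGammaStrikes(makeFrame(m), 4), "odd")
})

test_that("strike suppression never increases the raster maximum", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(rexp(400, 1 / 50), 20, 20)
    expect_lte(max(counts(suppressGammaStrikes(makeFrame(m)))), max(m))
  }
})

test_that("background subtraction: zero self-difference, clamp, contract", {
  set.seed(3)
  m <- matrix(rpois(100, 80), 10, 10)
  f <- makeFrame(m)
  expect_true(all(counts(subtractBackground(f, makeFrame(m))) == 0))
  # clamp: background exceeding the frame gives 0, not negatives
  hi <- makeFrame(m + 5); lo <- makeFrame(pmax(m - 5, 0))
  expect_true(all(counts(subtractBackground(lo, hi)) == 0))
  # unclamped diagnostic output preserves the signed difference
  d <- subtractBackground(lo, hi, clamp = FALSE)
  expect_true(all(frameMeta(d)$signed <= 0))
  # settings mismatch is the contract violation the acquisition rule forbids
  expect_error(subtractBackground(f, makeFrame(m, exposure = 300)),
               "settings")
  expect_error(subtractBackground(f, makeFrame(m, binning = 2L)), "settings")
  expect_error(subtractBackground(f, makeFrame(matrix(0, 5, 5))), "shape")
})

test_that("background subtraction removes the defective-pixel artefact", {
  ph <- phantomSpec(camera = cameraModel(gammaStrikeRate = 0))
  st <- acquisitionSettings(150, 1, "none")
  t0 <- injTime + 60 * 60
  fr <- renderView(ph, "anterior", st, t0, seed = 5)
  bg <- renderBackground(ph, st, seed = 6)
  expect_identical(counts(fr)[40, 200], 65535)
  expect_identical(counts(bg)[40, 200], 65535)
  sub <- subtractBackground(fr, bg)
  expect_identical(counts(sub)[40, 200], 0)
})

test_that("radiance calibration is linear in counts and inverse in exposure", {
  z <- countsToRadiance(makeFrame(matrix(0, 4, 4)))
  expect_true(all(radianceValues(z) == 0))
  m <- matrix(300, 4, 4)
  r150 <- countsToRadiance(makeFrame(m, exposure = 150))
  r300 <- countsToRadiance(makeFrame(m, exposure = 300))
  expect_equal(radianceValues(r150)[1, 1], 2.0)
  expect_equal(radianceValues(r300), radianceValues(r150) / 2)
  expect_equal(radianceValues(countsToRadiance(makeFrame(m), calibration = 4)),
               radianceValues(countsToRadiance(makeFrame(m))) / 4)
  expect_error(countsToRadiance(makeFrame(m), calibration = 0), "calibration")
})

test_that("bin-then-subtract equals subtract-then-bin on clamp-free frames", {
  set.seed(19)
  a <- matrix(rpois(144, 200) + 50, 12, 12)
  b <- matrix(rpois(144, 20), 12, 12)   # everywhere below the frame
  f <- makeFrame(a); g <- makeFrame(b, kind = "background")
  path1 <- counts(subtractBackground(binPixels(f, 3), binPixels(g, 3)))
  path2 <- counts(binPixels(subtractBackground(f, g), 3))
  expect_equal(path1, path2)
})

test_that("processing history is append-only provenance", {
  ph <- phantomSpec(camera = quietCamera())
  st <- acquisitionSettings(150, 8, "none")
  fr <- renderView(ph, "anterior", st, injTime + 3600, seed = 1)
  bg <- renderBackground(ph, st, seed = 2)
  map <- processFrame(fr, bg)
  h <- processingHistory(map)
  expect_identical(h[1], "acquired")
  expect_match(h[2], "suppress_strikes")
  expect_identical(h[3], "subtract_background")
  expect_identical(h[4], "counts_to_radiance")
})
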