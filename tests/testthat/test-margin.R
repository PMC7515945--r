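test_that("hotspot detection: degenerate, single blob, valley split, oracle", {
  # uniform map: degenerate background, no hotspots, no error
  expect_length(detectHotspots(makeMap(matrix(2, 16, 16))), 0)
  # one Gaussian blob 10 sd above background
  set.seed(43)
  base <- matrix(rnorm(32 * 32, 10, 0.5), 32, 32)
  rows <- matrix(1:32, 32, 32); cols <- t(rows)
  blob <- 5 * exp(-((rows - 16)^2 + (cols - 16)^2) / (2 * 3^2))
  mp <- makeMap(pmax(base + blob, 0))
  bg <- c(mean = 10, sd = 0.5)
  hs <- detectHotspots(mp, bg, kSigma = 3, minArea = 4)
  expect_length(hs, 1)
  peak <- which(mp@values == max(mp@values), arr.ind = TRUE)
  expect_true(any(hs[[1]]@pixels[, 1] == peak[1] &
                  hs[[1]]@pixels[, 2] == peak[2]))
  # two blobs separated by a sub-threshold valley -> two 4-connected spots
  two <- matrix(10, 32, 32)
  two <- two + 8 * exp(-((rows - 8)^2 + (cols - 16)^2) / (2 * 2^2)) +
    8 * exp(-((rows - 24)^2 + (cols - 16)^2) / (2 * 2^2))
  hs2 <- detectHotspots(makeMap(two), c(mean = 10, sd = 0.5))
  expect_length(hs2, 2)
  # component membership equals an independent threshold + BFS oracle
  thr <- 10 + 3 * 0.5
  lab <- oracleLabel4(two > thr)
  for (h in hs2) {
    ids <- unique(lab[h@pixels])
    expect_length(ids, 1)
    expect_equal(nrow(h@pixels), sum(lab == ids))
  }
})

test_that("filtered matching drives persistence", {
  set.seed(47)
  rows <- matrix(1:32, 32, 32); cols <- t(rows)
  blob <- 30 * exp(-((rows - 16)^2 + (cols - 16)^2) / (2 * 3^2))
  mU <- makeMap(matrix(10, 32, 32) + blob)
  h <- detectHotspots(mU, c(mean = 10, sd = 0.5))[[1]]
  # identical filtered map: persistent exactly when unfiltered TBR >= tau
  hSame <- matchFiltered(h, mU, c(mean = 10, sd = 0.5), tauPersist = 2)
  expect_true(isPersistent(hSame))
  expect_equal(hSame@tbrFiltered, h@tbrUnfiltered, tolerance = 1e-12)
  hHighTau <- matchFiltered(h, mU, c(mean = 10, sd = 0.5),
                            tauPersist = h@tbrUnfiltered + 0.1)
  expect_false(isPersistent(hHighTau))
  # flat filtered map: not persistent
  hFlat <- matchFiltered(h, makeMap(matrix(10, 32, 32)),
                         c(mean = 10, sd = 0.5), tauPersist = 2)
  expect_false(isPersistent(hFlat))
  expect_equal(hFlat@tbrFiltered, 1, tolerance = 1e-12)
  # geometry mismatch is a contract error
  expect_error(matchFiltered(h, makeMap(matrix(10, 8, 8)),
                             c(mean = 10, sd = 0.5)), "geometry")
})

test_that("view classification follows the persistence rule", {
  flat <- makeMap(matrix(5, 32, 32))
  expect_identical(verdict(classifyView(flat, flat)), "NSM")
  rows <- matrix(1:32, 32, 32); cols <- t(rows)
  set.seed(53)
  noise <- matrix(rnorm(1024, 0, 0.05), 32, 32)
  blob <- 20 * exp(-((rows - 16)^2 + (cols - 16)^2) / (2 * 3^2))
  mU <- makeMap(pmax(5 + blob + noise, 0))
  mFflat <- makeMap(pmax(5 + noise, 0))
  # hotspot on unfiltered only -> NSM, non-persistent rationale
  callN <- classifyView(mU, mFflat)
  expect_identical(verdict(callN), "NSM")
  expect_match(callN@rationale, "non-persistent")
  # hotspot persisting on the filtered map -> PSM suspected
  mFhot <- makeMap(pmax(2.5 + 0.6 * blob + noise, 0))
  callP <- classifyView(mU, mFhot)
  expect_identical(verdict(callP), "PSM_suspected")
  expect_true(any(vapply(hotspots(callP), isPersistent, logical(1))))
  # no filtered acquisition: verdict flagged low-confidence
  callL <- classifyView(mU, NULL)
  expect_match(callL@rationale, "LOW CONFIDENCE")
  expect_identical(verdict(callL), "PSM_suspected")
})

test_that("raising tau_persist never converts NSM into PSM_suspected", {
  for (s in 1:6) {
    pair <- renderViewPair(depth = c(0, 1, 3)[(s %% 3) + 1], seed = 300 + s)
    taus <- c(1, 1.5, 2, 3, 5)
    verdicts <- vapply(taus, function(tau)
      verdict(classifyView(pair$unfiltered, pair$filtered,
                           tauPersist = tau)), character(1))
    psm <- verdicts == "PSM_suspected"
    # once lost at some tau, PSM never reappears at a higher tau
    expect_true(all(diff(as.integer(psm)) <= 0))
  }
})

test_that("persistence separates surface from deep lesions", {
  for (s in 1:5) {
    surf <- renderViewPair(0, seed = 500 + s)
    deep <- renderViewPair(6, seed = 600 + s)
    expect_identical(verdict(classifyView(surf$unfiltered, surf$filtered)),
                     "PSM_suspected")
    expect_identical(verdict(classifyView(deep$unfiltered, deep$filtered)),
                     "NSM")
  }
})

test_that("specimen verdict is the OR over views", {
  expect_identical(classifySpecimen(list(makeCall("left", FALSE),
                                         makeCall("apical", TRUE))),
                   "PSM_suspected")
  expect_identical(classifySpecimen(list(makeCall("left", FALSE),
                                         makeCall("right", FALSE))),
                   "NSM")
})

test_that("truth scoring separates CLOSE views from plain errors", {
  truth <- c(left = "PSM", right = "NSM", anterior = "CLOSE",
             posterior = "NSM", basal = "PSM", apical = "CLOSE")
  calls <- list(makeCall("left", TRUE),      # TP
                makeCall("right", TRUE),     # FP
                makeCall("anterior", TRUE),  # CLOSE called
                makeCall("posterior", FALSE),# TN
                makeCall("basal", FALSE),    # FN
                makeCall("apical", FALSE))   # CLOSE not called
  got <- evaluateAgainstTruth(calls, truth)
  expect_identical(got, c(TP = 1L, FP = 1L, TN = 1L, FN = 1L,
                          CLOSE_called = 1L, CLOSE_not_called = 1L))
  # all-correct case has no errors
  perfect <- evaluateAgainstTruth(list(makeCall("left", TRUE),
                                       makeCall("right", FALSE)),
                                  c(left = "PSM", right = "NSM"))
  expect_identical(unname(perfect[c("FP", "FN")]), c(0L, 0L))
  expect_error(evaluateAgainstTruth(list(makeCall("left", TRUE)), truth),
               "same views")
})
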