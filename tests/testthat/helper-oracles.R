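# Independent brute-force oracles and small fixtures shared across tests.
# These deliberately re-derive results with naive loops / direct formulas,
# never through the package's own code paths.

# naive block-sum binning
oracleBinSum <- function(m, b) {
  nrb <- nrow(m) %/% b; ncb <- ncol(m) %/% b
  out <- matrix(0, nrb, ncb)
  for (i in seq_len(nrb)) for (j in seq_len(ncb)) {
    out[i, j] <- sum(m[((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)])
  }
  out
}

# symmetric padding by direct index arithmetic
oraclePadSym <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ref <- function(i, n) {
    # reflect with edge repetition: ... 2 1 | 1 2 ... n | n n-1 ...
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, nr + 2 * r, nc + 2 * r)
  for (i in seq_len(nr + 2 * r)) for (j in seq_len(nc + 2 * r)) {
    out[i, j] <- m[ref(i - r, nr), ref(j - r, nc)]
  }
  out
}

# direct (non-separable) windowed median
oracleMedian <- function(m, w) {
  r <- (w - 1) %/% 2
  p <- oraclePadSym(m, r)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- median(p[i:(i + 2 * r), j:(j + 2 * r)])
  }
  out
}

# direct 2-D Gaussian convolution (full 2-D kernel, 4-sigma truncation,
# symmetric padding)
oracleGauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  p <- oraclePadSym(m, r)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- sum(p[i:(i + 2 * r), j:(j + 2 * r)] * k2)
  }
  out
}

# breadth-first 4-connected labeling
oracleLabel4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (si in seq_len(nr)) for (sj in seq_len(nc)) {
    if (!mask[si, sj] || lab[si, sj] != 0L) next
    cur <- cur + 1L
    queue <- list(c(si, sj)); lab[si, sj] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- q[1] + d[1]; nj <- q[2] + d[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# camera with every stochastic artefact switched off
quietCamera <- function(...) {
  cameraModel(readNoiseSigma = 0, darkOffset = 0, gammaStrikeRate = 0,
              defectivePixels = matrix(integer(0), ncol = 2), ...)
}

# a minimal CLIFrame around a raw matrix
makeFrame <- function(m, exposure = 150, binning = 1L, filter = "none",
                      kind = "specimen", view = "anterior",
                      time = as.POSIXct("2020-01-01 10:00:00", tz = "UTC")) {
  new("CLIFrame", counts = m,
      settings = acquisitionSettings(exposure, binning, filter),
      acquisitionTime = time, kind = kind, view = view,
      history = "acquired", meta = list())
}

# a RadianceMap around a raw matrix
makeMap <- function(m, view = "anterior", exposure = 150, binning = 8L,
                    filter = "none") {
  new("RadianceMap", values = m,
      settings = acquisitionSettings(exposure, binning, filter),
      acquisitionTime = as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
      view = view, calibrationId = "test", history = character(0))
}

# margin call fixture honouring the verdict/persistence validity invariant
makeCall <- function(view, psm) {
  hs <- if (psm) {
    list(new("Hotspot", view = view, pixels = matrix(c(1L, 1L), ncol = 2),
             corePixels = matrix(c(1L, 1L), ncol = 2), peakRadiance = 10,
             tbrUnfiltered = 5, tbrFiltered = 5, persistent = TRUE))
  } else list()
  new("MarginCall", view = view,
      verdict = if (psm) "PSM_suspected" else "NSM",
      hotspots = hs, rationale = "fixture")
}

injTime <- as.POSIXct("2020-01-01 09:00:00", tz = "UTC")
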