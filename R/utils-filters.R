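# Low-level raster helpers shared by the imaging and margin stages.
# All filters use reflect boundary handling (edge row/col mirrored without
# repeating the border pixel would be "reflect101"; here the border pixel IS
# repeated, i.e. symmetric padding), chosen to avoid dark rims at specimen
# edges.

# symmetric (reflect) padding by r rows/cols on each side
.padReflect <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc)
    stop("padding radius exceeds raster size")
  ridx <- c(r:1, seq_len(nr), nr:(nr - r + 1L))
  cidx <- c(r:1, seq_len(nc), nc:(nc - r + 1L))
  m[ridx, cidx, drop = FALSE]
}

# 1-D Gaussian kernel truncated at 4 sigma, normalized
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with symmetric padding
.convolveSeparable <- function(m, k) {
  if (length(k) == 1L) return(m * k)
  r <- (length(k) - 1L) %/% 2L
  p <- .padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  # rows
  acc <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k))
    acc <- acc + k[i] * p[(i - 1L) + seq_len(nr), , drop = FALSE]
  # cols
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * acc[, (i - 1L) + seq_len(nc), drop = FALSE]
  out
}

# moving-window median via a full pairwise-exchange sort of the w^2 shifted
# rasters (vectorized; windows are small, 3x3 by default)
.medianFilter <- function(m, window) {
  if (window == 1L) return(m)
  r <- (window - 1L) %/% 2L
  p <- .padReflect(m, r)
  nr <- nrow(m); nc <- ncol(m)
  shifts <- vector("list", window * window)
  idx <- 1L
  for (dr in 0:(window - 1L)) for (dc in 0:(window - 1L)) {
    shifts[[idx]] <- p[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
    idx <- idx + 1L
  }
  k <- length(shifts)
  # bubble exchange network: after pass i the i largest are in place
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(shifts[[j]], shifts[[j + 1L]])
      hi <- pmax(shifts[[j]], shifts[[j + 1L]])
      shifts[[j]] <- lo
      shifts[[j + 1L]] <- hi
    }
  }
  shifts[[(k + 1L) %/% 2L]]
}

# 4-connected component labeling of a logical matrix; returns integer matrix
# with 0 = background, components numbered from 1 in raster-scan order
.labelComponents4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  stack <- integer(0)
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    labels[start] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      row <- ((cur - 1L) %% nr) + 1L
      col <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(if (row > 1L) cur - 1L,
                   if (row < nr) cur + 1L,
                   if (col > 1L) cur - nr,
                   if (col < nc) cur + nr)) {
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- nxt
          stack <- c(stack, nb)
        }
      }
    }
  }
  labels
}

# deterministic per-frame seed stream: one master seed expands to n child
# seeds via R's own RNG, restoring the caller's RNG state afterwards
.deriveSeeds <- function(master, n) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(master)
  sample.int(2147483646L, n)
}

# run expr with a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.minutesBetween <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}

# even-odd rule point-in-polygon for pixel centers; polygon is an n x 2
# matrix of (row, col) vertices; returns logical matrix over the raster
.rasterizePolygon <- function(polygon, nrow, ncol) {
  px <- as.vector(col(matrix(0, nrow, ncol)))  # x = col
  py <- as.vector(row(matrix(0, nrow, ncol)))  # y = row
  vx <- polygon[, 2]; vy <- polygon[, 1]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  matrix(inside, nrow, ncol)
}
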