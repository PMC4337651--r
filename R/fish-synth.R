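# Synthetic single-molecule FISH fixtures: non-overlapping elliptical
# cells in a 2D label mask, per-cell transcript counts rendered as
# anisotropic 3D Gaussian spots at sub-voxel positions, plus noise.
# Ground truth (per-cell counts, per-spot centroids, owning cells) is
# retained so detection can be scored exactly.

.PLACE_RETRIES <- 500L   # cell placement attempts per cell
.SPOT_RETRIES <- 200L    # spot placement attempts under minSeparation

# Sample non-overlapping elliptical cell footprints. Overlap is excluded
# conservatively through bounding circles (centre distance > sum of
# semi-major axes).
placeCells <- function(spec) {
  ny <- spec@dim[2L]
  nx <- spec@dim[3L]
  aPx <- spec@cellAxes[1L] / spec@voxelXY
  bPx <- spec@cellAxes[2L] / spec@voxelXY
  cells <- data.frame(cell = integer(), cx = numeric(), cy = numeric(),
                      a = numeric(), b = numeric(), angle = numeric())
  for (i in seq_len(spec@nCells)) {
    scale <- stats::runif(1, 0.85, 1.15)
    a <- aPx * scale
    b <- bPx * scale
    placed <- FALSE
    for (try in seq_len(.PLACE_RETRIES)) {
      cx <- stats::runif(1, a + 2, nx - a - 1)
      cy <- stats::runif(1, a + 2, ny - a - 1)
      if (nrow(cells) == 0L ||
          all(sqrt((cells$cx - cx)^2 + (cells$cy - cy)^2) >
              cells$a + a + 1)) {
        cells <- rbind(cells, data.frame(cell = i, cx = cx, cy = cy,
                                         a = a, b = b,
                                         angle = stats::runif(1, 0, pi)))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", spec@nCells, " non-overlapping cells in a ",
           ny, " x ", nx, " field; enlarge the field or reduce nCells")
  }
  cells
}

# Rasterize cell footprints into a 2D label mask (y, x).
maskFromCells <- function(cells, spec) {
  ny <- spec@dim[2L]
  nx <- spec@dim[3L]
  mask <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    ys <- max(1L, floor(cc$cy - cc$a)):min(ny, ceiling(cc$cy + cc$a))
    xs <- max(1L, floor(cc$cx - cc$a)):min(nx, ceiling(cc$cx + cc$a))
    dy <- outer(ys - cc$cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cc$cx)
    # rotate into the ellipse frame
    u <- dx * cos(cc$angle) + dy * sin(cc$angle)
    v <- -dx * sin(cc$angle) + dy * cos(cc$angle)
    inside <- (u / cc$a)^2 + (v / cc$b)^2 <= 1
    sub <- mask[ys, xs]
    sub[inside] <- cc$cell
    mask[ys, xs] <- sub
  }
  mask
}

# One uniform draw inside the (rotated) ellipse footprint of a cell,
# inset by one pixel so the rounded pixel centre of any spot always
# falls on the cell's own mask label.
drawInCell <- function(cc) {
  a <- max(cc$a - 1, 0.5)
  b <- max(cc$b - 1, 0.5)
  r <- sqrt(stats::runif(1))
  th <- stats::runif(1, 0, 2 * pi)
  u <- a * r * cos(th)
  v <- b * r * sin(th)
  c(y = cc$cy + u * sin(cc$angle) + v * cos(cc$angle),
    x = cc$cx + u * cos(cc$angle) - v * sin(cc$angle))
}

# Sample sub-voxel spot positions for all transcripts, enforcing the
# minimum pairwise separation by rejection with bounded retries; if no
# candidate clears the constraint the farthest-from-neighbours candidate
# is kept (recorded honestly in the ground truth).
sampleSpotPositions <- function(cells, counts, spec) {
  nz <- spec@dim[1L]
  sigZ <- spec@sigmaAxial / spec@voxelZ
  zLo <- 1 + 2 * sigZ
  zHi <- nz - 2 * sigZ
  if (zHi <= zLo) stop("stack too shallow for the axial PSF")
  placed <- matrix(numeric(), ncol = 3L)
  rows <- vector("list", sum(counts))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    for (s in seq_len(counts[i])) {
      best <- NULL
      bestDist <- -Inf
      for (try in seq_len(.SPOT_RETRIES)) {
        yx <- drawInCell(cc)
        z <- stats::runif(1, zLo, zHi)
        cand <- c(z, yx[["y"]], yx[["x"]])
        d <- if (nrow(placed) == 0L) Inf
             else min(sqrt(colSums((t(placed) - cand)^2)))
        if (d >= spec@minSeparation) {
          best <- cand
          bestDist <- d
          break
        }
        if (d > bestDist) {
          best <- cand
          bestDist <- d
        }
      }
      placed <- rbind(placed, best)
      k <- k + 1L
      rows[[k]] <- data.frame(cell = cc$cell, z = best[1L], y = best[2L],
                              x = best[3L])
    }
  }
  if (k == 0L)
    return(data.frame(cell = integer(), z = numeric(), y = numeric(),
                      x = numeric()))
  do.call(rbind, rows)
}

# Add anisotropic Gaussian spots to an intensity array (z, y, x).
renderSpots <- function(img, positions, amplitude, sigZ, sigXY) {
  if (nrow(positions) == 0L) return(img)
  d <- dim(img)
  wz <- ceiling(4 * sigZ)
  wxy <- ceiling(4 * sigXY)
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    zs <- max(1L, floor(p$z - wz)):min(d[1L], ceiling(p$z + wz))
    ys <- max(1L, floor(p$y - wxy)):min(d[2L], ceiling(p$y + wxy))
    xs <- max(1L, floor(p$x - wxy)):min(d[3L], ceiling(p$x + wxy))
    gz <- exp(-(zs - p$z)^2 / (2 * sigZ^2))
    gy <- exp(-(ys - p$y)^2 / (2 * sigXY^2))
    gx <- exp(-(xs - p$x)^2 / (2 * sigXY^2))
    blob <- amplitude * outer(gz, outer(gy, gx))
    img[zs, ys, xs] <- img[zs, ys, xs] + blob
  }
  img
}

applyNoise <- function(img, spec) {
  if (spec@noiseModel == "gaussian") {
    if (spec@noiseSd > 0)
      img <- img + stats::rnorm(length(img), sd = spec@noiseSd)
    pmax(img, 0)
  } else {
    array(stats::rpois(length(img), lambda = pmax(img, 0)), dim = dim(img))
  }
}

renderChannel <- function(spec, cells, counts) {
  img <- array(spec@background, dim = spec@dim)
  spots <- sampleSpotPositions(cells, counts, spec)
  sigZ <- spec@sigmaAxial / spec@voxelZ
  sigXY <- spec@sigmaLateral / spec@voxelXY
  img <- renderSpots(img, spots, spec@amplitude, sigZ, sigXY)
  falseSpots <- data.frame(z = numeric(), y = numeric(), x = numeric())
  if (spec@falseSpotRate > 0 && spec@nCells > 0L) {
    nFalse <- stats::rpois(1, spec@falseSpotRate * spec@nCells)
    if (nFalse > 0L) {
      falseSpots <- data.frame(
        z = stats::runif(nFalse, 1 + 2 * sigZ, spec@dim[1L] - 2 * sigZ),
        y = stats::runif(nFalse, 1 + 2 * sigXY, spec@dim[2L] - 2 * sigXY),
        x = stats::runif(nFalse, 1 + 2 * sigXY, spec@dim[3L] - 2 * sigXY))
      img <- renderSpots(img, falseSpots, spec@amplitude, sigZ, sigXY)
    }
  }
  img <- applyNoise(img, spec)
  list(stack = ImageStack(img, voxelXY = spec@voxelXY,
                          voxelZ = spec@voxelZ),
       spots = spots, falseSpots = falseSpots)
}

#' Generate a synthetic FISH stack with ground truth
#'
#' Places `nCells` non-overlapping elliptical cells, renders each
#' transcript of `counts` as an anisotropic 3D Gaussian at a uniform
#' random sub-voxel position inside its cell's footprint (uniform in z
#' away from the axial margins), adds noise, and returns the stack, the
#' 2D cell-label mask and the full ground truth.
#'
#' @param spec a [StackSpec-class] object.
#' @param counts integer vector of per-cell transcript counts
#'   (`length(counts) == nCells`), e.g. from [sampleCounts()].
#' @param seed explicit RNG seed.
#' @return A list with elements `stack` ([ImageStack-class]), `mask`
#'   (integer label matrix, 0 = background), `cells` (footprint geometry),
#'   and `truth`: a list of `spots` (per-spot `cell`, sub-voxel `z`, `y`,
#'   `x`), `cellCounts` and `falseSpots`. The number of true spots always
#'   equals `sum(counts)`.
#' @examples
#' fx <- generateStack(StackSpec(dim = c(16, 96, 96), nCells = 3L),
#'                     counts = c(2L, 0L, 1L), seed = 7)
#' nrow(fx$truth$spots)  # 3
#' @export
generateStack <- function(spec, counts, seed) {
  stopifnot(is(spec, "StackSpec"))
  validObject(spec)
  if (length(counts) != spec@nCells)
    stop("'counts' must have one entry per cell (nCells = ",
         spec@nCells, ")")
  withSeed(seed, {
    cells <- placeCells(spec)
    mask <- maskFromCells(cells, spec)
    ch <- renderChannel(spec, cells, as.integer(counts))
    list(stack = ch$stack, mask = mask, cells = cells,
         truth = list(
           spots = ch$spots,
           cellCounts = data.frame(cell = cells$cell,
                                   count = as.integer(counts)),
           falseSpots = ch$falseSpots))
  })
}

#' Generate a two-channel FISH fixture over one shared cell mask
#'
#' Emulates dual-probe hybridization: two differentially labelled probe
#' sets imaged over the same cells. Per-cell counts are drawn
#' independently for each channel from its count model; both channels are
#' rendered over the identical cell geometry and mask.
#'
#' @param modelA,modelB [CountModel-class] objects for the two channels.
#' @param spec a [StackSpec-class] object shared by both channels.
#' @param seed explicit RNG seed.
#' @return A list with shared `mask` and `cells`, and per-channel entries
#'   `channelA`/`channelB`, each holding `stack`, `counts` and `truth` as
#'   in [generateStack()].
#' @export
makeTwoChannelFixture <- function(modelA, modelB, spec, seed) {
  stopifnot(is(modelA, "CountModel"), is(modelB, "CountModel"),
            is(spec, "StackSpec"))
  seed <- checkSeed(seed)
  withSeed(seed, {
    countsA <- sampleCountsImpl(modelA, spec@nCells)
    countsB <- sampleCountsImpl(modelB, spec@nCells)
    cells <- placeCells(spec)
    mask <- maskFromCells(cells, spec)
    chA <- renderChannel(spec, cells, countsA)
    chB <- renderChannel(spec, cells, countsB)
    wrap <- function(ch, counts) list(
      stack = ch$stack, counts = counts,
      truth = list(spots = ch$spots,
                   cellCounts = data.frame(cell = cells$cell,
                                           count = counts),
                   falseSpots = ch$falseSpots))
    list(mask = mask, cells = cells,
         channelA = wrap(chA, countsA), channelB = wrap(chB, countsB))
  })
}
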