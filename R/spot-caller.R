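# 3D Laplacian-of-Gaussian spot calling: band-pass filtering that
# enhances diffraction-limited blobs, fixed-threshold detection with a
# size gate, splitting of merged components at sufficiently separated
# local maxima (so overlapping transcripts are resolved in three
# dimensions), per-cell assignment through a 2D label mask, and
# per-cell count summaries.

# Sampled anisotropic LoG kernel, negated so bright blobs give positive
# extrema, and shifted to zero sum so constant images map to zero.
logKernel3d <- function(sigmaVox) {
  hw <- pmax(1L, ceiling(4 * sigmaVox))
  ax <- lapply(seq_len(3L), function(i) seq(-hw[i], hw[i]))
  s2 <- sigmaVox^2
  g <- function(v, i) exp(-v^2 / (2 * s2[i]))
  gz <- g(ax[[1L]], 1L); gy <- g(ax[[2L]], 2L); gx <- g(ax[[3L]], 3L)
  G <- outer(gz, outer(gy, gx))
  d <- dim(G)
  quad <- function(v, i) (v^2 - s2[i]) / s2[i]^2
  qz <- array(rep(quad(ax[[1L]], 1L), times = d[2L] * d[3L]), dim = d)
  qy <- array(rep(rep(quad(ax[[2L]], 2L), each = d[1L]), times = d[3L]),
              dim = d)
  qx <- array(rep(quad(ax[[3L]], 3L), each = d[1L] * d[2L]), dim = d)
  k <- -G * (qz + qy + qx)
  k - mean(k)
}

# Same-size 3D convolution via FFT with replicate-padding (constant
# inputs stay constant at the boundary, so a zero-sum kernel returns an
# exactly flat response).
fftConvSame <- function(arr, kern) {
  d <- dim(arr)
  kd <- dim(kern)
  hw <- (kd - 1L) %/% 2L
  P <- vapply(seq_len(3L),
              function(i) stats::nextn(d[i] + 2L * hw[i], c(2, 3, 5)),
              numeric(1))
  idx <- lapply(seq_len(3L),
                function(i) pmin(pmax(seq_len(P[i]) - hw[i], 1L), d[i]))
  padded <- arr[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  kp <- array(0, dim = P)
  kidx <- lapply(seq_len(3L),
                 function(i) ((seq(-hw[i], hw[i])) %% P[i]) + 1L)
  kp[kidx[[1L]], kidx[[2L]], kidx[[3L]]] <- kern
  out <- Re(stats::fft(stats::fft(padded) * stats::fft(kp),
                       inverse = TRUE)) / prod(P)
  out[hw[1L] + seq_len(d[1L]), hw[2L] + seq_len(d[2L]),
      hw[3L] + seq_len(d[3L]), drop = FALSE]
}

#' Apply a 3D Laplacian-of-Gaussian filter to an image stack
#'
#' The physical sigmas (micrometres) are converted to voxel units per
#' axis, honouring the anisotropy between the lateral voxel size and the
#' z step. The sign convention is fixed so that bright blobs yield
#' positive extrema, and the kernel is zero-sum so a constant stack maps
#' to a zero response.
#'
#' @param stack an [ImageStack-class] object.
#' @param sigmaLateral,sigmaAxial Gaussian scales in micrometres; the
#'   defaults match the generator's default PSF.
#' @return An [ImageStack-class] holding the filtered response.
#' @examples
#' st <- ImageStack(array(1, dim = c(8, 16, 16)))
#' max(abs(stackData(logFilter3d(st))))  # ~0
#' @export
logFilter3d <- function(stack, sigmaLateral = 0.12, sigmaAxial = 0.24) {
  stopifnot(is(stack, "ImageStack"))
  if (sigmaLateral <= 0 || sigmaAxial <= 0)
    stop("filter sigmas must be positive")
  sigmaVox <- c(sigmaAxial / stack@voxelZ,
                sigmaLateral / stack@voxelXY,
                sigmaLateral / stack@voxelXY)
  kern <- logKernel3d(sigmaVox)
  if (any(dim(kern) > dim(stack@data)))
    stop("LoG kernel (", paste(dim(kern), collapse = " x "),
         ") exceeds the stack dimensions")
  ImageStack(fftConvSame(stack@data, kern), voxelXY = stack@voxelXY,
             voxelZ = stack@voxelZ)
}

#' Propose a detection threshold from the filtered background
#'
#' The filtered response of background voxels is centred near zero;
#' spots are sparse, so a robust scale estimate of the whole response is
#' effectively the background scale. The proposal is
#' `median + k * MAD`. The threshold actually applied is explicit user
#' input stored in the experiment configuration; this helper only
#' suggests a starting value.
#'
#' @param filtered an [ImageStack-class] of LoG responses.
#' @param k multiple of the MAD above the median.
#' @return Proposed threshold (response units).
#' @export
proposeThreshold <- function(filtered, k = 8) {
  stopifnot(is(filtered, "ImageStack"))
  v <- as.numeric(filtered@data)
  stats::median(v) + k * stats::mad(v)
}

# Flags, per above-threshold voxel, whether it is a 26-neighbourhood
# local maximum of the response.
localMaxFlags <- function(arr, coords) {
  d <- dim(arr)
  val <- arr[coords]
  isMax <- rep(TRUE, nrow(coords))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- cbind(coords[, 1L] + dz, coords[, 2L] + dy, coords[, 3L] + dx)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    nbVal <- rep(-Inf, nrow(coords))
    nbVal[ok] <- arr[nb[ok, , drop = FALSE]]
    isMax <- isMax & val >= nbVal
  }
  isMax
}

#' Detect spots in a filtered stack
#'
#' Voxels above the threshold are grouped by 3D 26-connectivity;
#' components outside the admissible size range are discarded.
#' Components containing multiple sufficiently separated, sufficiently
#' prominent local maxima are split into one call per maximum, which
#' resolves transcripts that overlap in a 2D projection but are separated
#' in z. Centroids are intensity-weighted over the component voxels,
#' reported in voxel coordinates (z first, origin at the stack corner,
#' 1-based).
#'
#' @param filtered an [ImageStack-class] of LoG responses (see
#'   [logFilter3d()]).
#' @param threshold positive response threshold. One stored threshold per
#'   channel should be reused across all samples of an experiment.
#' @param sizeRange admissible component size `[min, max]` in voxels;
#'   the default derives from the default PSF at the default voxel size.
#' @param splitProminence minimum height of a secondary local maximum,
#'   as a fraction of the component peak, for it to seed its own call.
#' @param splitMinDist minimum distance (voxels) between surviving
#'   maxima.
#' @return A data frame of spot calls: `z`, `y`, `x` (sub-voxel
#'   centroid), `size` (voxels), `response` (peak filtered value) and
#'   `cell` (0 until assigned).
#' @seealso [assignSpotsToCells()], [scoreDetection()]
#' @export
detectSpots <- function(filtered, threshold, sizeRange = c(4, 200),
                        splitProminence = 0.3, splitMinDist = 2) {
  stopifnot(is(filtered, "ImageStack"))
  if (threshold <= 0) stop("'threshold' must be positive")
  if (length(sizeRange) != 2L || sizeRange[1L] <= 0 ||
      sizeRange[1L] > sizeRange[2L])
    stop("'sizeRange' must satisfy 0 < min <= max")
  arr <- filtered@data
  empty <- data.frame(z = numeric(), y = numeric(), x = numeric(),
                      size = integer(), response = numeric(),
                      cell = integer())
  above <- which(arr > threshold)
  if (length(above) == 0L) return(empty)
  coords <- arrayInd(above, dim(arr))
  comp <- labelComponents(coords, dim(arr))
  isMax <- localMaxFlags(arr, coords)
  val <- arr[coords]
  calls <- list()
  for (members in split(seq_along(comp), comp)) {
    if (length(members) < sizeRange[1L] || length(members) > sizeRange[2L])
      next
    cc <- coords[members, , drop = FALSE]
    cv <- val[members]
    peak <- max(cv)
    maxima <- members[isMax[members] & val[members] >=
                        splitProminence * peak]
    if (length(maxima) == 0L)
      maxima <- members[which.max(cv)]
    # greedy suppression of maxima closer than splitMinDist
    maxima <- maxima[order(val[maxima], decreasing = TRUE)]
    kept <- maxima[1L]
    for (m in maxima[-1L]) {
      dd <- sqrt(colSums((t(coords[kept, , drop = FALSE]) -
                          as.numeric(coords[m, ]))^2))
      if (all(dd >= splitMinDist)) kept <- c(kept, m)
    }
    if (length(kept) == 1L) {
      assign <- rep(1L, length(members))
    } else {
      km <- coords[kept, , drop = FALSE]
      assign <- apply(cc, 1L, function(v)
        which.min(colSums((t(km) - v)^2)))
    }
    for (j in seq_along(kept)) {
      sel <- assign == j
      w <- cv[sel]
      calls[[length(calls) + 1L]] <- data.frame(
        z = sum(cc[sel, 1L] * w) / sum(w),
        y = sum(cc[sel, 2L] * w) / sum(w),
        x = sum(cc[sel, 3L] * w) / sum(w),
        size = sum(sel), response = max(w), cell = 0L)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Assign spot calls to cells through a 2D label mask
#'
#' Each spot is assigned the mask label at the rounded (y, x) of its
#' centroid. Spots over background (label 0) are retained in the spot
#' table but excluded from the per-cell counts.
#'
#' @param spots spot-call data frame from [detectSpots()].
#' @param mask integer label matrix (y, x); must cover the stack's
#'   lateral extent.
#' @return A list with `spots` (the table with `cell` filled in) and
#'   `counts` (data frame `cell`, `count` covering every labelled cell,
#'   including zeros).
#' @export
assignSpotsToCells <- function(spots, mask) {
  if (!is.matrix(mask)) stop("'mask' must be a 2D label matrix")
  labels <- sort(unique(mask[mask > 0]))
  if (nrow(spots)) {
    ry <- round(spots$y)
    rx <- round(spots$x)
    if (any(ry < 1 | ry > nrow(mask) | rx < 1 | rx > ncol(mask)))
      stop("spot centroids fall outside the mask extent; ",
           "mask and stack shapes disagree")
    spots$cell <- mask[cbind(ry, rx)]
  }
  counts <- vapply(labels, function(l) sum(spots$cell == l), integer(1))
  list(spots = spots,
       counts = data.frame(cell = as.integer(labels), count = counts))
}

#' Summarize per-cell transcript counts
#'
#' @param counts integer vector of spots per cell (one entry per cell).
#' @return A [FISHSummary-class]: mean spots per cell, sample (n-1)
#'   variance, percentage of cells with more than zero / more than one
#'   spot, and the dispersion index (variance over mean).
#' @examples
#' summarizeCounts(c(0, 0, 0, 4))
#' @export
summarizeCounts <- function(counts) {
  if (length(counts) == 0L || anyNA(counts))
    stop("'counts' must be a non-empty vector without NAs")
  m <- mean(counts)
  v <- if (length(counts) >= 2L) stats::var(counts) else NA_real_
  new("FISHSummary", meanSpots = m, varianceSpots = v,
      pctPositive = 100 * mean(counts > 0),
      pctMultiple = 100 * mean(counts > 1),
      nCells = length(counts),
      dispersionIndex = if (m > 0) v / m else NA_real_)
}

#' Score detected spots against ground truth
#'
#' Greedy one-to-one matching: candidate call/truth pairs within the
#' match radius are accepted in order of increasing distance, each call
#' and each true spot matching at most once. Unmatched truth counts as a
#' false negative, unmatched calls as false positives.
#'
#' @param spots spot-call data frame (columns `z`, `y`, `x`).
#' @param truth ground-truth spot data frame (columns `z`, `y`, `x`),
#'   e.g. `fx$truth$spots` from [generateStack()].
#' @param matchRadius maximum centroid distance (voxels) for a match.
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1` and
#'   `undefinedPrecision` (TRUE when there are no calls, in which case
#'   precision is `NA`).
#' @export
scoreDetection <- function(spots, truth, matchRadius = 3) {
  nC <- nrow(spots)
  nT <- nrow(truth)
  if (nC == 0L)
    return(list(tp = 0L, fp = 0L, fn = nT, precision = NA_real_,
                recall = if (nT > 0L) 0 else NA_real_, f1 = NA_real_,
                undefinedPrecision = TRUE))
  cm <- as.matrix(spots[, c("z", "y", "x")])
  tm <- as.matrix(truth[, c("z", "y", "x")])
  dd <- outer(rowSums(cm^2), rowSums(tm^2), "+") - 2 * cm %*% t(tm)
  dd <- sqrt(pmax(dd, 0))
  pairs <- which(dd <= matchRadius, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs)) {
    pairs <- pairs[order(dd[pairs]), , drop = FALSE]
    usedC <- logical(nC)
    usedT <- logical(nT)
    for (i in seq_len(nrow(pairs))) {
      ci <- pairs[i, 1L]
      ti <- pairs[i, 2L]
      if (!usedC[ci] && !usedT[ti]) {
        usedC[ci] <- TRUE
        usedT[ti] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nC - tp
  fn <- nT - tp
  precision <- tp / nC
  recall <- if (nT > 0L) tp / nT else NA_real_
  f1 <- if (is.na(recall) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, undefinedPrecision = FALSE)
}
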