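# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Direct shift-and-add 3D convolution with replicate padding (the
# package path is FFT-based). The kernels used here are even-symmetric,
# so convolution and correlation coincide.
directConv3d <- function(arr, kern) {
  d <- dim(arr)
  kd <- dim(kern)
  hw <- (kd - 1L) %/% 2L
  idx <- lapply(1:3, function(i)
    pmin(pmax(seq_len(d[i] + 2L * hw[i]) - hw[i], 1L), d[i]))
  padded <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out <- array(0, d)
  for (a in seq_len(kd[1])) for (b in seq_len(kd[2]))
    for (cc in seq_len(kd[3])) {
      w <- kern[a, b, cc]
      if (w == 0) next
      out <- out + w * padded[(a - 1L) + seq_len(d[1]),
                              (b - 1L) + seq_len(d[2]),
                              (cc - 1L) + seq_len(d[3]), drop = FALSE]
    }
  out
}

# Maximum-cardinality matching within a radius by exhaustive branch and
# bound (the package path is greedy nearest-first matching).
bruteMaxMatches <- function(calls, truth, radius) {
  nC <- nrow(calls)
  nT <- nrow(truth)
  if (nC == 0L || nT == 0L) return(0L)
  cm <- as.matrix(calls[, c("z", "y", "x")])
  tm <- as.matrix(truth[, c("z", "y", "x")])
  dd <- sqrt(pmax(outer(rowSums(cm^2), rowSums(tm^2), "+") -
                  2 * cm %*% t(tm), 0))
  best <- 0L
  rec <- function(ci, usedT, tp) {
    if (tp + (nC - ci + 1L) <= best) return()
    if (ci > nC) {
      best <<- max(best, tp)
      return()
    }
    for (ti in which(!usedT & dd[ci, ] <= radius)) {
      usedT[ti] <- TRUE
      rec(ci + 1L, usedT, tp + 1L)
      usedT[ti] <- FALSE
    }
    rec(ci + 1L, usedT, tp)
  }
  rec(1L, logical(nT), 0L)
  best
}

# Closed-form pooled-variance two-sample t statistic.
handT <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Expected greenFraction of an explicit-tree colony from its event list:
# switched subtrees are disjoint (events only occur in unswitched cells)
# and switching is irreversible, so each single-progeny event at
# generation g contributes exactly 2^-g of the final cells and each
# both-progeny event 2^-(g-1).
greenFractionFromEvents <- function(outcome) {
  if (outcome@founderPreSwitched) return(1)
  ev <- switchEvents(outcome)
  if (nrow(ev) == 0L) return(0)
  sum(ifelse(ev$progeny == "both", 2^(1 - ev$generation),
             2^(-ev$generation)))
}

# Small rendered stack with spots at known sub-voxel positions.
makeSpotStack <- function(positions, spec = StackSpec(), noiseSeed = NULL) {
  arr <- array(spec@background, dim = spec@dim)
  arr <- sectorFISH:::renderSpots(
    arr, positions, spec@amplitude,
    spec@sigmaAxial / spec@voxelZ, spec@sigmaLateral / spec@voxelXY)
  if (!is.null(noiseSeed)) {
    set.seed(noiseSeed)
    arr <- pmax(arr + rnorm(length(arr), sd = spec@noiseSd), 0)
  }
  ImageStack(arr, voxelXY = spec@voxelXY, voxelZ = spec@voxelZ)
}
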