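test_that("a constant stack has zero LoG response everywhere", {
  st <- ImageStack(array(137.5, dim = c(16L, 24L, 24L)))
  expect_lt(max(abs(stackData(logFilter3d(st)))), 1e-10 * 137.5)
})

test_that("the LoG filter is linear", {
  spec <- StackSpec(dim = c(16L, 48L, 48L), nCells = 0L)
  st <- makeSpotStack(data.frame(z = 8.2, y = 24.7, x = 20.1), spec,
                      noiseSeed = 1)
  r1 <- stackData(logFilter3d(st))
  r2 <- stackData(logFilter3d(ImageStack(2 * stackData(st))))
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
})

test_that("FFT filtering equals direct dense convolution on a 32^3 stack", {
  set.seed(2)
  arr <- array(runif(32^3, 0, 100), dim = c(32L, 32L, 32L))
  st <- ImageStack(arr, voxelXY = 0.13, voxelZ = 0.2)
  sigmaVox <- c(0.24 / 0.2, 0.12 / 0.13, 0.12 / 0.13)
  kern <- sectorFISH:::logKernel3d(sigmaVox)
  expect_equal(stackData(logFilter3d(st)), directConv3d(arr, kern),
               tolerance = 1e-8)
})

test_that("the response peaks within one voxel of a matched spot", {
  spec <- StackSpec(dim = c(24L, 48L, 48L), nCells = 0L)
  truth <- data.frame(z = 12.4, y = 25.2, x = 22.8)
  st <- makeSpotStack(truth, spec)
  filt <- stackData(logFilter3d(st))
  am <- arrayInd(which.max(filt), dim(filt))
  expect_lt(max(abs(am - unlist(truth))), 1)
})

test_that("kernels larger than the stack are rejected", {
  st <- ImageStack(array(1, dim = c(4L, 24L, 24L)))
  expect_error(logFilter3d(st), "exceeds")
  expect_error(logFilter3d(ImageStack(array(1, c(16, 24, 24))),
                           sigmaLateral = -1), "positive")
})

test_that("well-separated noise-free spots are each called once", {
  spec <- StackSpec(dim = c(24L, 64L, 64L), nCells = 0L, noiseSd = 0)
  truth <- data.frame(z = c(8, 12, 16, 10, 14),
                      y = c(12.3, 30.6, 48.2, 50.5, 18.9),
                      x = c(14.8, 44.1, 20.4, 52.7, 33.2))
  st <- makeSpotStack(truth, spec)
  filt <- logFilter3d(st)
  spots <- detectSpots(filt, proposeThreshold(filt))
  expect_identical(nrow(spots), 5L)
  sc <- scoreDetection(spots, truth, matchRadius = 1)
  expect_identical(sc$tp, 5L)
})

test_that("a blank stack yields no calls at any positive threshold", {
  st <- ImageStack(array(100, dim = c(16L, 32L, 32L)))
  filt <- logFilter3d(st)
  expect_identical(nrow(detectSpots(filt, 1)), 0L)
  expect_error(detectSpots(filt, 0), "positive")
  expect_error(detectSpots(filt, 1, sizeRange = c(5, 2)), "min <= max")
})

test_that("spots separated only along z are resolved in 3D", {
  spec <- StackSpec(dim = c(28L, 48L, 48L), nCells = 0L)
  truth <- data.frame(z = c(12, 16), y = c(24.3, 24.3), x = c(24.6, 24.6))
  st <- makeSpotStack(truth, spec, noiseSeed = 3)  # SNR 10
  filt <- logFilter3d(st)
  spots <- detectSpots(filt, proposeThreshold(filt))
  expect_identical(nrow(spots), 2L)
  expect_identical(scoreDetection(spots, truth, matchRadius = 2)$tp, 2L)
})

test_that("the number of calls is non-increasing in the threshold", {
  spec <- StackSpec(dim = c(20L, 96L, 96L), nCells = 3L)
  fx <- generateStack(spec, c(4L, 3L, 5L), seed = 12)
  filt <- logFilter3d(fx$stack)
  base <- proposeThreshold(filt)
  ncalls <- vapply(base * c(0.25, 0.5, 1, 2, 4, 8),
                   function(th) nrow(detectSpots(filt, th)), integer(1))
  expect_true(all(diff(ncalls) <= 0))
})

test_that("spot-to-cell assignment respects the mask and conserves counts", {
  mask <- matrix(0L, 40, 40)
  mask[5:15, 5:15] <- 7L
  mask[25:35, 25:35] <- 2L
  spots <- data.frame(z = c(5, 5, 5), y = c(10.2, 30.4, 20),
                      x = c(10.8, 30.1, 20), size = 8L, response = 1,
                      cell = 0L)
  res <- assignSpotsToCells(spots, mask)
  expect_identical(res$spots$cell, c(7L, 2L, 0L))
  expect_identical(res$counts$count[res$counts$cell == 7L], 1L)
  expect_identical(res$counts$count[res$counts$cell == 2L], 1L)
  # background spot excluded from counts but kept in the table
  expect_identical(sum(res$counts$count) + sum(res$spots$cell == 0L),
                   nrow(spots))
  # no spots: every labelled cell reports zero
  res0 <- assignSpotsToCells(spots[0, ], mask)
  expect_identical(res0$counts$count, c(0L, 0L))
  # centroids outside the mask extent flag a shape mismatch
  far <- transform(spots, y = y + 100)
  expect_error(assignSpotsToCells(far, mask), "mask")
})

test_that("count summaries report the documented statistics", {
  s <- summarizeCounts(c(0, 0, 0, 4))
  expect_equal(s@meanSpots, 1)
  expect_equal(s@varianceSpots, 4)
  expect_equal(s@pctPositive, 25)
  expect_equal(s@pctMultiple, 25)
  expect_equal(s@dispersionIndex, 4)
  s0 <- summarizeCounts(rep(0, 10))
  expect_equal(s0@meanSpots, 0)
  expect_equal(s0@pctPositive, 0)
  expect_true(is.na(s0@dispersionIndex))
  expect_error(summarizeCounts(numeric()))
  # Poisson counts have dispersion index near 1
  po <- sampleCounts(CountModel("poisson", mean = 7.3), 1e4, seed = 13)
  di <- summarizeCounts(po)@dispersionIndex
  expect_gt(di, 0.9)
  expect_lt(di, 1.1)
})

test_that("detection scoring handles perfect, empty and mixed calls", {
  truth <- data.frame(z = c(5, 10, 15), y = c(10, 20, 30),
                      x = c(10, 20, 30))
  perfect <- scoreDetection(truth, truth, matchRadius = 1)
  expect_identical(perfect$precision, 1)
  expect_identical(perfect$recall, 1)
  none <- scoreDetection(truth[0, ], truth, matchRadius = 1)
  expect_identical(none$recall, 0)
  expect_true(none$undefinedPrecision)
  expect_true(is.na(none$precision))
})

test_that("greedy matching agrees with exhaustive matching", {
  set.seed(14)
  for (i in 1:10) {
    truth <- data.frame(z = runif(8, 1, 20), y = runif(8, 1, 40),
                        x = runif(8, 1, 40))
    # jittered calls for 6 of the 8 truths plus 2 false positives
    calls <- truth[1:6, ] + matrix(runif(18, -0.8, 0.8), ncol = 3)
    calls <- rbind(calls, data.frame(z = runif(2, 1, 20),
                                     y = runif(2, 1, 40),
                                     x = runif(2, 1, 40)))
    sc <- scoreDetection(calls, truth, matchRadius = 2)
    expect_identical(sc$tp, bruteMaxMatches(calls, truth, 2))
  }
})
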