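smallSpec <- function(...) {
  StackSpec(dim = c(16L, 160L, 160L), nCells = 4L, ...)
}

test_that("zero counts and zero noise give a flat background stack", {
  spec <- smallSpec(noiseSd = 0)
  fx <- generateStack(spec, rep(0L, 4), seed = 1)
  expect_true(all(stackData(fx$stack) == spec@background))
  expect_identical(nrow(fx$truth$spots), 0L)
})

test_that("a noise-free spot peaks within one voxel of its true centre", {
  spec <- smallSpec(noiseSd = 0)
  fx <- generateStack(spec, c(1L, 0L, 0L, 0L), seed = 2)
  tr <- fx$truth$spots
  am <- arrayInd(which.max(stackData(fx$stack)), spec@dim)
  expect_lt(max(abs(am - c(tr$z, tr$y, tr$x))), 1)
})

test_that("every transcript is rendered: spot count equals count sum", {
  spec <- StackSpec(dim = c(20L, 320L, 320L), nCells = 15L)
  counts <- sampleCounts(CountModel("poisson", mean = 7.3), 15, seed = 3)
  fx <- generateStack(spec, counts, seed = 4)
  expect_identical(nrow(fx$truth$spots), as.integer(sum(counts)))
  expect_identical(sum(fx$truth$cellCounts$count), as.integer(sum(counts)))
})

test_that("stacks are bit-identical under identical seeds", {
  spec <- smallSpec()
  a <- generateStack(spec, c(2L, 1L, 0L, 3L), seed = 5)
  b <- generateStack(spec, c(2L, 1L, 0L, 3L), seed = 5)
  expect_identical(stackData(a$stack), stackData(b$stack))
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth$spots, b$truth$spots)
})

test_that("true spot centroids lie inside their owning cell's mask", {
  spec <- StackSpec(dim = c(20L, 320L, 320L), nCells = 12L)
  counts <- sampleCounts(CountModel("negbin", mean = 12, variance = 53),
                         12, seed = 6)
  fx <- generateStack(spec, counts, seed = 7)
  tr <- fx$truth$spots
  lab <- fx$mask[cbind(round(tr$y), round(tr$x))]
  expect_identical(lab, tr$cell)
})

test_that("the minimum spot separation is honoured at moderate density", {
  spec <- smallSpec(minSeparation = 6)
  fx <- generateStack(spec, c(3L, 3L, 2L, 3L), seed = 8)
  pos <- as.matrix(fx$truth$spots[, c("z", "y", "x")])
  dmat <- as.matrix(dist(pos))
  expect_gte(min(dmat[upper.tri(dmat)]), 6)
})

test_that("impossible cell packings raise a placement error", {
  spec <- StackSpec(dim = c(12L, 48L, 48L), nCells = 6L)
  expect_error(generateStack(spec, rep(0L, 6), seed = 9),
               "non-overlapping")
})

test_that("two-channel fixtures share one mask and are reproducible", {
  spec <- smallSpec()
  blank <- CountModel("poisson", mean = 0)
  busy <- CountModel("poisson", mean = 6)
  fx <- makeTwoChannelFixture(blank, busy, spec, seed = 10)
  expect_true(all(stackData(fx$channelA$stack) <=
                  spec@background + 6 * spec@noiseSd))
  expect_identical(sum(fx$channelA$counts), 0L)
  expect_gt(sum(fx$channelB$counts), 0L)
  expect_identical(nrow(fx$channelB$truth$spots),
                   as.integer(sum(fx$channelB$counts)))
  fx2 <- makeTwoChannelFixture(blank, busy, spec, seed = 10)
  expect_identical(stackData(fx$channelB$stack),
                   stackData(fx2$channelB$stack))
  expect_identical(fx$mask, fx2$mask)
})

test_that("poisson photon noise respects the rendered intensity scale", {
  spec <- smallSpec(noiseModel = "poisson", background = 50)
  fx <- generateStack(spec, rep(0L, 4), seed = 11)
  v <- as.numeric(stackData(fx$stack))
  expect_lt(abs(mean(v) - 50), 1)
  expect_lt(abs(var(v) / mean(v) - 1), 0.1)
})
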