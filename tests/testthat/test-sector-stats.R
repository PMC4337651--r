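test_that("the half-sector frequency is the printed ratio", {
  expect_equal(halfSectorFrequency(SectorCounts(1267, 2, 3)), 2 / 1264)
  expect_equal(halfSectorFrequency(SectorCounts(500, 0, 10)), 0)
  expect_error(halfSectorFrequency(SectorCounts(10, 0, 10)),
               "degenerate")
  expect_error(SectorCounts(10, 6, 6), "exceed")
})

test_that("adding fully green colonies never changes the estimate", {
  set.seed(11)
  for (i in 1:25) {
    total <- sample(100:5000, 1)
    half <- rbinom(1, total, 0.01)
    green <- rbinom(1, total - half, 0.02)
    k <- sample(0:500, 1)
    base <- halfSectorFrequency(SectorCounts(total, half, green))
    bumped <- halfSectorFrequency(SectorCounts(total + k, half,
                                               green + k))
    expect_identical(bumped, base)
  }
})

test_that("replicate summaries use the mean and sample SD", {
  est <- summarizeReplicates(c(0.0015, 0.0016, 0.00164))
  expect_equal(rateMean(est), 0.00158)
  expect_equal(rateSD(est), sqrt(5.2e-9), tolerance = 1e-10)
  expect_identical(est@nReplicates, 3L)
  expect_identical(rateSD(summarizeReplicates(rep(0.004, 4))), 0)
  expect_error(summarizeReplicates(numeric()))
  expect_warning(est1 <- summarizeReplicates(0.002), "single replicate")
  expect_true(is.na(rateSD(est1)))
})

test_that("fold changes are scale equivariant and match printed ratios", {
  expect_equal(foldChange(0.0042, 0.0042)$fold, 1)
  expect_equal(foldChange(0.055, 0.00158)$fold, 34.81, tolerance = 1e-3)
  expect_equal(foldChange(0.0111, 0.00158)$fold, 7.025, tolerance = 1e-3)
  a <- summarizeReplicates(c(0.05, 0.06, 0.055))
  b <- summarizeReplicates(c(0.001, 0.0015, 0.002))
  scaleUp <- function(x, k) summarizeReplicates(rateReplicates(x) * k)
  expect_equal(foldChange(scaleUp(a, 7), scaleUp(b, 7))$fold,
               foldChange(a, b)$fold)
  expect_true(is.finite(foldChange(a, b)$se))
  expect_error(foldChange(a, 0), "positive")
})

test_that("the t test matches the closed form on random small samples", {
  set.seed(99)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -2, 2))
    res <- twoSampleT(a, b)
    expect_lt(abs(res$statistic - handT(a, b)), 1e-10)
    expect_false(res$degenerate)
  }
  same <- c(0.1, 0.2, 0.3)
  res <- twoSampleT(same, same)
  expect_identical(res$statistic, 0)
  expect_identical(res$p.value, 1)
  # zero pooled variance with different means: infinite t, p -> 0
  res <- twoSampleT(c(1, 1), c(2, 2))
  expect_true(res$degenerate)
  expect_identical(res$p.value, 0)
  expect_identical(res$statistic, -Inf)
  expect_error(twoSampleT(1, c(1, 2)), "two replicates")
})

test_that("simulation plus estimation recovers the generative rate", {
  p <- 0.01
  est <- recoverRate(SwitchParams(pDiv = p), 1e5, 3, seed = 21)
  se <- sqrt(p * (1 - p) / 3e5)
  expect_lt(abs(rateMean(est) - p), 3 * se)
  expect_identical(rateMean(recoverRate(SwitchParams(pDiv = 0), 1e4, 3,
                                        seed = 22)), 0)
  # fully green colonies from pre-switched founders are excluded by the
  # denominator, so the estimate is unaffected by qPre
  estQ <- recoverRate(SwitchParams(pDiv = p, qPre = 0.5), 1e5, 3,
                      seed = 23)
  seQ <- sqrt(p * (1 - p) / (3e5 * 0.5))
  expect_lt(abs(rateMean(estQ) - p), 3 * seQ)
})

test_that("the estimator is unbiased at small rates", {
  p <- 1e-3
  est <- recoverRate(SwitchParams(pDiv = p), 1e5, 200, seed = 31)
  expect_lt(abs(rateMean(est) - p) / p, 0.05)
})

test_that("bootstrap intervals bracket the point estimate reproducibly", {
  countsList <- lapply(1:3, function(r)
    simulatePopulation(SwitchParams(pDiv = 0.01), 2e4, seed = 40 + r,
                       replicateId = paste0("rep", r)))
  est <- bootstrapRateCI(countsList, nBoot = 500L, seed = 50)
  ci <- est@ci
  expect_identical(ci[1L], 0.95)
  expect_lt(ci[2L], rateMean(est))
  expect_gt(ci[3L], rateMean(est))
  expect_lt(ci[3L] - ci[2L], 0.01)
  est2 <- bootstrapRateCI(countsList, nBoot = 500L, seed = 50)
  expect_identical(est@ci, est2@ci)
})

test_that("sector counts round-trip through the CSV reader", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(replicate_id = c("a", "b"),
                       total_colonies = c(1267, 900),
                       half_sectored = c(2, 1), fully_green = c(3, 0)),
            f, row.names = FALSE)
  lst <- readSectorCounts(f)
  expect_length(lst, 2L)
  est <- estimateRate(lst)
  expect_equal(rateReplicates(est), c(2 / 1264, 1 / 900))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(readSectorCounts(bad), "lacks columns")
})
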