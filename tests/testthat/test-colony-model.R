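test_that("degenerate parameter settings force the expected colony class", {
  # no events possible
  o <- simulateColony(SwitchParams(pDiv = 0, generations = 6L), seed = 1)
  expect_identical(colonyClass(o), "red")
  expect_identical(greenFraction(o), 0)
  expect_identical(nrow(switchEvents(o)), 0L)
  # forced single event at the first (and only) division
  o <- simulateColony(SwitchParams(pDiv = 1, generations = 1L), seed = 2)
  expect_identical(colonyClass(o), "half_sector")
  expect_identical(greenFraction(o), 0.5)
  expect_identical(switchEvents(o)$generation, 1L)
  # founder switched before plating
  for (s in 1:5) {
    o <- simulateColony(SwitchParams(pDiv = 0.5, qPre = 1,
                                     generations = 5L), seed = s)
    expect_identical(colonyClass(o), "full_green")
    expect_identical(greenFraction(o), 1)
  }
})

test_that("invalid parameters and missing seeds are rejected", {
  expect_error(SwitchParams(pDiv = 1.2), "0, 1")
  expect_error(SwitchParams(pDiv = 0.1, qPre = -0.5), "0, 1")
  expect_error(SwitchParams(pDiv = 0.1, generations = 0L), "generations")
  expect_error(simulateColony(SwitchParams(pDiv = 0.1)), "seed")
  expect_error(simulatePopulation(SwitchParams(pDiv = 0.1), 10,
                                  seed = NULL), "seed")
})

test_that("switching is irreversible and heritable in explicit trees", {
  # Disjointness of switched subtrees plus irreversibility imply the
  # final green fraction is exactly the sum of 2^-g (single progeny) or
  # 2^-(g-1) (both progeny) over events; any reversion or failure to
  # inherit would break the identity.
  for (s in 1:30) {
    o <- simulateColony(SwitchParams(pDiv = 0.15, generations = 6L),
                        seed = s)
    expect_identical(greenFraction(o), greenFractionFromEvents(o))
  }
  for (s in 1:30) {
    o <- simulateColony(SwitchParams(pDiv = 0.15, generations = 6L,
                                     timingModel = "cell_cycle"),
                        seed = 100 + s)
    expect_identical(greenFraction(o), greenFractionFromEvents(o))
  }
})

test_that("half-sector frequency and green fraction are monotone in pDiv", {
  # common random numbers: same seed across the rate ladder
  n <- 1e5
  rates <- c(1e-4, 1e-3, 1e-2, 1e-1)
  res <- lapply(rates, function(p) {
    tab <- simulateColonyTable(SwitchParams(pDiv = p), n, seed = 42)
    c(half = mean(tab$class == "half_sector"),
      green = mean(tab$greenFraction))
  })
  half <- vapply(res, `[[`, numeric(1), "half")
  green <- vapply(res, `[[`, numeric(1), "green")
  expect_true(all(diff(half) > 0))
  expect_true(all(diff(green) > 0))
})

test_that("thinned and explicit-tree simulators agree in distribution", {
  n <- 1e4
  p <- SwitchParams(pDiv = 0.02, generations = 8L)
  thin <- simulateColonyTable(p, n, seed = 7, method = "thinned")
  tree <- simulateColonyTable(p, n, seed = 7001, method = "tree")
  for (cls in c("red", "half_sector", "partial_sector")) {
    f1 <- mean(thin$class == cls)
    f2 <- mean(tree$class == cls)
    pooled <- (f1 + f2) / 2
    se <- sqrt(2 * pooled * (1 - pooled) / n)
    expect_lt(abs(f1 - f2), 3 * max(se, 1e-4))
  }
  # green fractions also agree in mean
  seGf <- sqrt(var(thin$greenFraction) / n + var(tree$greenFraction) / n)
  expect_lt(abs(mean(thin$greenFraction) - mean(tree$greenFraction)),
            3 * seGf)
})

test_that("population tallies match degenerate expectations", {
  counts <- simulatePopulation(SwitchParams(pDiv = 0), 1000, seed = 3)
  tl <- sectorTallies(counts)
  expect_identical(tl[["total"]], 1000L)
  expect_identical(tl[["red"]], 1000L)
  expect_identical(tl[["half_sectored"]], 0L)
  expect_identical(tl[["fully_green"]], 0L)
  # pre-switched founders appear as fully green at the binomial rate
  counts <- simulatePopulation(SwitchParams(pDiv = 0, qPre = 0.05), 1e5,
                               seed = 4)
  fg <- sectorTallies(counts)[["fully_green"]]
  expect_lt(abs(fg - 5000), 3 * sqrt(1e5 * 0.05 * 0.95))
  # half-sector tally at the per-division rate
  counts <- simulatePopulation(SwitchParams(pDiv = 0.01), 1e5, seed = 5)
  hs <- sectorTallies(counts)[["half_sectored"]]
  expect_lt(abs(hs - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
})

test_that("cell-cycle pattern labels respect the replication phase", {
  p <- SwitchParams(pDiv = 0.25, generations = 6L,
                    timingModel = "cell_cycle", fPreReplication = 0.25,
                    gfpDelay = 0.5)
  events <- do.call(rbind, lapply(1:40, function(s)
    switchEvents(simulateColony(p, seed = s))))
  expect_gt(nrow(events), 20)
  # both-progeny switches arise only pre-replication, single-progeny
  # switches only post-replication
  expect_true(all(events$phase[events$progeny == "both"] ==
                  "pre_replication"))
  expect_true(all(events$phase[events$progeny != "both"] ==
                  "post_replication"))
  pat <- classifySwitchPattern(events, p)
  both <- pat$progeny == "both"
  expect_true(all(pat$pattern[both] %in% c(3L, 6L, NA)))
  expect_true(all(pat$pattern[!both] %in% c(1L, 2L, 4L, 5L, 7L, 8L)))
  # small-budded detection of a pre-replication event is pattern 6
  small6 <- pat$budStage == "small_budded" & both
  expect_true(any(small6))
  expect_true(all(pat$pattern[small6] == 6L))
  # large-budded single-progeny events fall in the 7/8 family
  large <- pat$budStage == "large_budded" & !both
  expect_true(all(pat$pattern[large] %in% c(7L, 8L)))
})

test_that("pattern classification rejects simple-mode events", {
  p <- SwitchParams(pDiv = 1, generations = 1L)
  ev <- switchEvents(simulateColony(p, seed = 1))
  expect_error(classifySwitchPattern(ev, p), "cell_cycle")
  # no events: no pattern, zero rows
  pcc <- SwitchParams(pDiv = 0.1, timingModel = "cell_cycle")
  expect_identical(nrow(classifySwitchPattern(NULL, pcc)), 0L)
})

test_that("fraction-based classification mirrors the event-based classes", {
  expect_identical(classifyByFraction(c(0, 1, 0.5, 0.47, 0.25)),
                   c("red", "full_green", "half_sector", "half_sector",
                     "partial_sector"))
  expect_identical(classifyByFraction(0.4, tol = 0.1), "half_sector")
  expect_error(classifyByFraction(1.2))
})
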