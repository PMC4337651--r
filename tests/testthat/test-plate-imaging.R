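test_that("rendered plates round-trip through the colony counter", {
  for (n in c(10L, 100L)) {
    classes <- rep(c("red", "half_sector", "partial_sector",
                     "full_green"), length.out = n)
    pr <- renderPlate(classes, seed = n)
    expect_identical(countColonies(pr@composite, 0.5), n)
  }
  # larger plating on a bigger scan
  classes <- rep(c("red", "full_green"), length.out = 250L)
  pr <- renderPlate(classes,
                    geometry = list(imageSize = 1024L,
                                    radiusRange = c(8, 14),
                                    background = 0.05, level = 1),
                    seed = 99)
  expect_identical(countColonies(pr@composite, 0.5), 250L)
})

test_that("the GFP channel only counts colonies with green area", {
  classes <- c(rep("red", 5), rep("full_green", 4), rep("half_sector", 3))
  pr <- renderPlate(classes, seed = 17)
  expect_identical(countColonies(pr@gfp, 0.5), 7L)
})

test_that("blank scans count zero colonies", {
  pr <- renderPlate(character(0), seed = 1)
  expect_true(all(pr@gfp == 0.05))
  expect_identical(suppressWarnings(countColonies(pr@gfp, 0.5)), 0L)
})

test_that("touching colonies merge into a single component", {
  img <- matrix(0, 64, 64)
  for (ctr in list(c(20, 25), c(20, 41))) {  # radius 8, centres 16 apart
    yy <- outer(seq_len(64) - ctr[1], rep(1, 64))
    xx <- outer(rep(1, 64), seq_len(64) - ctr[2])
    img[yy^2 + xx^2 <= 64] <- 1
  }
  expect_identical(countColonies(img, 0.5), 1L)
})

test_that("a half-sector wedge covers half the disk area", {
  pr <- renderPlate("half_sector",
                    geometry = list(imageSize = 128L,
                                    radiusRange = c(20, 20),
                                    background = 0, level = 1),
                    seed = 23)
  greenArea <- sum(pr@gfp > 0.5)
  diskArea <- pi * 20^2
  expect_lt(abs(greenArea - diskArea / 2) / (diskArea / 2), 0.05)
})

test_that("the count is non-increasing in the minimum area", {
  pr <- renderPlate(rep("full_green", 40), seed = 31)
  counts <- vapply(c(1L, 20L, 100L, 200L, 1000L),
                   function(a) countColonies(pr@gfp, 0.5, minArea = a),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1L], 40L)
})
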