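test_that("summed-volume box sums match direct summation", {
  expect_equal(boxSum(buildSummedVolume(array(1, c(4, 4, 4))),
                      c(1, 1, 1), c(4, 4, 4)), 64)
  expect_true(all(boxSum(buildSummedVolume(array(0, c(3, 3, 3))),
                         rbind(c(1, 1, 1), c(2, 2, 2)),
                         rbind(c(2, 2, 2), c(3, 3, 3))) == 0))
  set.seed(13)
  p <- array(rnorm(6^3), c(6, 6, 6))
  svt <- buildSummedVolume(p)
  for (trial in 1:50) {
    lo <- sapply(1:3, function(a) sample.int(6, 1))
    hi <- lo + sapply(1:3, function(a) sample.int(6 - lo[a] + 1, 1)) - 1L
    expect_equal(boxSum(svt, lo, hi),
                 sum(p[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]),
                 tolerance = 1e-9)
  }
  expect_error(buildSummedVolume(array(c(NaN, rep(1, 7)), c(2, 2, 2))),
               "finite")
})

test_that("cuboid goodness evaluates the coverage-size tradeoff", {
  expect_equal(cuboidGoodness(8, c(2, 2, 2)), 8 / 36)
  expect_equal(cuboidGoodness(0, c(5, 3, 2)), 0)
  g4 <- cuboidGoodness(64, c(4, 4, 4))
  expect_equal(g4, 64 / 144)
  expect_gt(g4, cuboidGoodness(8, c(2, 2, 2)))   # denser coverage wins
  expect_error(cuboidGoodness(1, c(0, 2, 2)), ">= 1")
  expect_equal(cuboidGoodness(8, c(2, 2, 2), penalty = "slice"), 2)
})

test_that("stride-1 search equals the exhaustive brute-force argmax", {
  set.seed(23)
  for (trial in 1:5) {
    n <- sample(5:7, 3, replace = TRUE)
    p <- array(runif(prod(n)), n)
    reg <- CuboidRegion(c(1, 1, 1), n)
    got <- searchBestCuboid(vg(p), reg, stride = 1L, minDim = 3L)
    want <- bfBestCuboid(p, minDim = 3L)
    expect_identical(got$region@lo, as.integer(want$lo))
    expect_identical(got$region@hi, as.integer(want$hi))
    expect_equal(got$cg, want$cg, tolerance = 1e-12)
  }
})

test_that("concentrated bone mass is recovered exactly", {
  p <- array(0, c(10, 10, 10))
  p[4:7, 3:6, 5:8] <- 1
  got <- searchBestCuboid(vg(p), CuboidRegion(c(1, 1, 1), c(10, 10, 10)),
                          stride = 1L)
  expect_identical(got$region@lo, c(4L, 3L, 5L))
  expect_identical(got$region@hi, c(7L, 6L, 8L))
  # stride 2 with refinement still finds it
  got2 <- searchBestCuboid(vg(p), CuboidRegion(c(1, 1, 1), c(10, 10, 10)),
                           stride = 2L)
  expect_identical(got2$region@lo, c(4L, 3L, 5L))
  expect_identical(got2$region@hi, c(7L, 6L, 8L))
})

test_that("degenerate all-zero volumes fall back to the tie rules", {
  p <- array(0, c(6, 6, 6))
  got <- searchBestCuboid(vg(p), CuboidRegion(c(1, 1, 1), c(6, 6, 6)),
                          stride = 1L, minDim = 3L)
  expect_identical(got$region@lo, c(1L, 1L, 1L))
  expect_identical(got$region@hi, c(3L, 3L, 3L))
  expect_equal(got$cg, 0)
})

test_that("goodness before refinement never improves on a coarser lattice", {
  set.seed(31)
  p <- array(runif(12^3), c(12, 12, 12))
  reg <- CuboidRegion(c(1, 1, 1), c(12, 12, 12))
  cgs <- sapply(c(1L, 2L, 3L, 4L), function(st)
    searchBestCuboid(vg(p), reg, stride = st, refine = FALSE)$cg)
  expect_true(all(diff(cgs) <= 1e-12))
})

test_that("initial search region follows the padded-bounds rule", {
  d <- c(40, 40, 60)
  head <- array(0, d); head[5:35, 6:36, 3:58] <- 1
  air <- array(0, d); air[18:24, 10:14, 20:30] <- 1
  reg <- initialSearchRegion(vg(head), vg(air), marginSlices = 5L)
  expect_identical(reg@lo, c(13L, 6L, 15L))
  expect_identical(reg@hi, c(29L, 21L, 35L))   # anterior half: (6+36)/2
  # clipping to the head box
  air2 <- array(0, d); air2[6:8, 10:14, 4:6] <- 1
  reg2 <- initialSearchRegion(vg(head), vg(air2), marginSlices = 5L)
  expect_identical(reg2@lo[3], 3L)
  expect_error(initialSearchRegion(vg(head), vg(array(0, d))), "empty")
})

test_that("fitted cuboid recovers the phantom sinus compartment", {
  s <- generateSubject(phantomSpec(), 1)
  del <- delineateAirCavities(s@probmaps)
  reg0 <- initialSearchRegion(headMask(s@probmaps), del$mask)
  # the search region contains the whole true compartment
  tb <- s@meta$sinusBox
  expect_true(all(reg0@lo <= tb@lo) && all(reg0@hi >= tb@hi))
  fit <- searchBestCuboid(probMap(s@probmaps, "bone"), reg0, stride = 2L)
  expect_gte(dice(cuboidMask(fit$region, s@mri),
                  s@truthMasks$sinusCompartment), 0.6)
})
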