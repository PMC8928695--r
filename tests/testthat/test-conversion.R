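# draw a synthetic (mri, hu) sample from a known curve
drawSample <- function(n, mLow, mHigh, margin = 80, mriSd = 0, huSd = 0,
                       seed = 1) {
  set.seed(seed)
  mri <- runif(n, mLow - margin, mHigh + margin)
  hu <- pmin(pmax((mri - mLow) / (mHigh - mLow), 0), 1) * 1000 - 1000
  data.frame(mri = mri + rnorm(n, sd = mriSd), hu = hu + rnorm(n, sd = huSd))
}

test_that("prediction follows the three-segment curve", {
  m <- ConversionModel(100, 300)
  expect_equal(predictHu(m, 90), -1000)
  expect_equal(predictHu(m, 310), 0)
  expect_equal(predictHu(m, 200), -500)
  x <- seq(-100, 600, by = 0.25)
  y <- predictHu(m, x)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= -1000 & y <= 0))
  expect_error(ConversionModel(300, 100), "below")
})

test_that("point-curve distance matches a dense-sampling oracle", {
  scales <- c(mri = 1, hu = 1)   # unit scales for hand-checkable geometry
  # on the diagonal -> 0
  expect_equal(pointCurveDistance(c(0.5, -500), c(0, 1),
                                  scales = c(mri = 1, hu = 1000)), 0,
               tolerance = 1e-12)
  # left plateau extends leftward -> 0
  expect_equal(pointCurveDistance(c(-3, -1000), c(0, 1),
                                  scales = c(mri = 1, hu = 1000)), 0,
               tolerance = 1e-12)
  set.seed(77)
  for (trial in 1:8) {
    a <- runif(1, 50, 150); b <- a + runif(1, 80, 250)
    pt <- c(runif(1, a - 100, b + 100), runif(1, -1400, 400))
    sc <- c(mri = 200, hu = 1000)
    got <- pointCurveDistance(pt, c(a, b), scales = sc)
    want <- curveDistOracle(pt, a, b, sc)
    expect_equal(got, want, tolerance = 1e-3)
  }
  # corner geometry: point directly below the upper breakpoint
  got <- pointCurveDistance(c(300, -500), c(100, 300),
                            scales = c(mri = 1, hu = 1))
  want <- curveDistOracle(c(300, -500), 100, 300,
                          c(mri = 1, hu = 1), plateauLen = 1000)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("noise-free samples on the lattice are recovered exactly", {
  sm <- drawSample(200, 120, 320)
  # force a lattice containing the truth
  scales <- conversionScales(sm$mri)
  est <- fitOnce(rbind(sm, data.frame(mri = c(120, 320),
                                      hu = c(-1000, 0))))
  expect_lt(abs(est[["mLow"]] - 120), 2)
  expect_lt(abs(est[["mHigh"]] - 320), 2)
  expect_error(fitOnce(sm[1:5, ]), "at least 10")
  expect_error(fitOnce(sm[0, ]), "empty|at least")
})

test_that("plateau-only samples are flagged ill-posed", {
  sm <- data.frame(mri = runif(50, 0, 400),
                   hu = rep(c(-1000, 0), 25))
  sm <- sm[order(sm$mri), ]
  sm$hu <- ifelse(sm$mri < 200, -1000, 0)
  expect_warning(fitOnce(sm), "ill-posed")
})

test_that("noisy recovery stays within 5 percent of the truth", {
  sm <- drawSample(400, 120, 320, mriSd = 10, huSd = 40, seed = 3)
  est <- fitOnce(sm)
  expect_lt(abs(est[["mLow"]] - 120) / 120, 0.05)
  expect_lt(abs(est[["mHigh"]] - 320) / 320, 0.05)
})

test_that("bootstrap is seeded, averaged and guarded", {
  sm <- drawSample(500, 120, 320, mriSd = 10, huSd = 40, seed = 4)
  b1 <- fitBootstrap(sm, nReps = 10L, seed = 99)
  b2 <- fitBootstrap(sm, nReps = 10L, seed = 99)
  expect_identical(breakpoints(b1), breakpoints(b2))
  expect_identical(b1@fitMeta$perRepeat, b2@fitMeta$perRepeat)
  expect_gt(sd(b1@fitMeta$perRepeat[, 1]), 0)
  expect_lt(abs(b1@mLow - 120) / 120, 0.05)
  expect_lt(abs(b1@mHigh - 320) / 320, 0.05)
  expect_error(fitBootstrap(sm[1:50, ], nVox = 100L), "fewer voxels")
  # bootstrap leaves the caller's RNG state untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(fitBootstrap(sm, nReps = 2L, seed = 5))
  expect_identical(runif(1), before)
})

test_that("cohort averaging and leave-one-out reduce as specified", {
  smA <- drawSample(300, 120, 320, mriSd = 10, huSd = 40, seed = 5)
  smB <- drawSample(300, 120, 320, mriSd = 10, huSd = 40, seed = 6)
  # single subject: cohort model equals that subject's bootstrap model
  solo <- fitCohort(list(smA), seed = 10, nReps = 5L)
  direct <- fitBootstrap(smA, seed = 10 + 7919L, nReps = 5L)
  expect_equal(breakpoints(solo), breakpoints(direct))
  # identical subjects: cohort equals either
  twin <- fitCohort(list(smA, smA), seed = 10, nReps = 5L)
  m1 <- twin@fitMeta$subjectBreakpoints
  expect_equal(breakpoints(twin)[["mLow"]], mean(m1[, 1]))
  # cohort of 2, holding out subject 1 -> the other subject's model alone
  loo <- leaveOneOut(list(smA, smB), 1, seed = 10, nReps = 5L)
  only <- fitCohort(list(smB), seed = 10, nReps = 5L)
  expect_equal(breakpoints(loo), breakpoints(only))
  expect_identical(loo@fitMeta$heldOut, 1L)
  # the held-out subject's data cannot influence its model
  smA2 <- smA; smA2$hu <- smA2$hu + 500
  loo2 <- leaveOneOut(list(smA2, smB), 1, seed = 10, nReps = 5L)
  expect_equal(breakpoints(loo), breakpoints(loo2))
  expect_error(leaveOneOut(list(smA), 1), "at least 2")
  expect_error(leaveOneOut(list(smA, smB), 3, nReps = 2L), "out of range")
})

test_that("estimation bias vanishes as noise vanishes", {
  errAt <- function(huSd, mriSd) {
    sm <- drawSample(400, 120, 320, mriSd = mriSd, huSd = huSd, seed = 8)
    est <- fitBootstrap(sm, nReps = 10L, seed = 11)
    abs(est@mLow - 120) + abs(est@mHigh - 320)
  }
  errs <- c(errAt(0, 0), errAt(40, 10), errAt(120, 30))
  expect_lt(errs[1], 4)            # near-exact at zero noise
  expect_lt(errs[1], errs[3] + 1)  # no worse than the noisiest setting
})

test_that("models serialize to JSON and back", {
  sm <- drawSample(200, 120, 320, mriSd = 5, huSd = 20, seed = 9)
  m <- fitBootstrap(sm, nReps = 3L, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  writeConversionModel(m, f)
  m2 <- readConversionModel(f)
  expect_equal(breakpoints(m2), breakpoints(m))
  expect_equal(m2@fitMeta$nReps, 3L)
})
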