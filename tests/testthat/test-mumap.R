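lb <- tissueLabels()

test_that("tissue classification matches a direct truth-table evaluation", {
  # exhaustive over a coarse probability grid for every class
  vals <- c(0, 0.3, 0.6)
  grid <- expand.grid(brain = vals, soft = vals, bone = vals, air = vals)
  d <- c(nrow(grid), 1, 1)
  pm <- makeProbSet(d,
                    grey = array(grid$brain, d),
                    soft = array(grid$soft, d),
                    bone = array(grid$bone, d),
                    air = array(grid$air, d))
  lab <- classifyTissues(pm)@data[, 1, 1]
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    if (g$brain >= 0.5) lb[["brain"]]
    else if (g$bone >= 0.25) lb[["bone"]]
    else if (g$soft >= 0.5) lb[["soft"]]
    else lb[["air"]]
  }, integer(1))
  expect_identical(as.integer(lab), as.integer(expected))
})

test_that("classification precedence and defaults behave as specified", {
  # bone probability 0.30, all others below their thresholds -> bone
  pm <- makeProbSet(c(2, 2, 2), bone = 0.30)
  expect_true(all(classifyTissues(pm)@data == lb[["bone"]]))
  # all zero -> air
  pm0 <- makeProbSet(c(2, 2, 2))
  expect_true(all(classifyTissues(pm0)@data == lb[["air"]]))
  # brain 0.6 beats bone 0.3
  pmB <- makeProbSet(c(2, 2, 2), grey = 0.6, bone = 0.3)
  expect_true(all(classifyTissues(pmB)@data == lb[["brain"]]))
})

test_that("classification is idempotent over one-hot probability maps", {
  set.seed(3)
  d <- c(5, 5, 5)
  labArr <- array(sample(0:3, prod(d), TRUE), d)
  pm <- makeProbSet(d,
                    grey = array(as.numeric(labArr == lb[["brain"]]), d),
                    soft = array(as.numeric(labArr == lb[["soft"]]), d),
                    bone = array(as.numeric(labArr == lb[["bone"]]), d),
                    air = array(as.numeric(labArr == lb[["air"]]), d))
  expect_identical(classifyTissues(pm)@data, array(as.numeric(labArr), d))
})

test_that("attenuation lookup matches direct enumeration", {
  co <- muCoefficients()
  allBone <- vg(array(lb[["bone"]], c(3, 3, 3)))
  expect_true(all(assignMu(allBone)@mu@data == 0.151))
  allAir <- vg(array(lb[["air"]], c(3, 3, 3)))
  expect_true(all(assignMu(allAir)@mu@data == 0))
  set.seed(1)
  mixed <- vg(array(sample(0:3, 8, TRUE), c(2, 2, 2)))
  m <- assignMu(mixed)
  lut <- c(co[["air"]], co[["soft"]], co[["brain"]], co[["bone"]])
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_identical(m@mu@data[i, j, k],
                     lut[mixed@data[i, j, k] + 1])
  expect_error(assignMu(vg(array(7, c(2, 2, 2)))), "unknown label")
})

test_that("bulk sinus assignment sets exactly the masked voxels to 0.100", {
  labels <- vg(array(lb[["bone"]], c(4, 4, 4)))
  m <- assignMu(labels)
  mask <- array(0, c(4, 4, 4)); mask[2:3, 2:3, 2] <- 1
  mb <- applyBulkSinus(m, vg(mask))
  expect_true(all(mb@mu@data[mask == 1] == 0.100))
  expect_equal(sum(mb@mu@data != m@mu@data), sum(mask))
  expect_true(all(mb@labels@data[mask == 1] == lb[["bulkSinus"]]))
  empty <- applyBulkSinus(m, vg(array(0, c(4, 4, 4))))
  expect_identical(empty@mu@data, m@mu@data)
})

test_that("model conversion maps bone voxels to the air-soft mix", {
  model <- ConversionModel(100, 300)
  d <- c(4, 4, 4)
  labels <- vg(array(lb[["bone"]], d))
  m <- assignMu(labels)
  mri <- array(200, d)      # midpoint -> -500 HU -> 0.048
  mri[1, 1, 1] <- 50        # below mLow -> -1000 HU -> 0
  mri[2, 1, 1] <- 350       # above mHigh -> 0 HU -> 0.096
  region <- CuboidRegion(c(1, 1, 1), d)
  mc <- applyConvertedSinus(m, region, vg(mri), model)
  expect_equal(mc@mu@data[1, 1, 1], 0)
  expect_equal(mc@mu@data[2, 1, 1], 0.096)
  expect_equal(mc@mu@data[3, 3, 3], 0.048)
  expect_true(all(mc@labels@data == lb[["convertedSinus"]]))
  # non-bone voxels inside the region are untouched
  labels2 <- vg(array(lb[["soft"]], d))
  m2 <- applyConvertedSinus(assignMu(labels2), region, vg(mri), model)
  expect_true(all(m2@mu@data == 0.096))
  expect_true(all(m2@labels@data == lb[["soft"]]))
  # converted values stay within [air, soft] coefficients
  expect_true(all(mc@mu@data >= 0 & mc@mu@data <= 0.096))
})

test_that("bilinear scaling anchors air, water and the bone boundary", {
  expect_equal(huToMu(-1000), 0)
  expect_equal(huToMu(0), 0.096, tolerance = 1e-3)
  expect_equal(huToMu(157), 0.105, tolerance = 0.01 * 0.105)
  expect_equal(huToMu(-1500), 0)  # clamped at the air floor
  hu <- seq(-1024, 2000, by = 0.5)
  mu <- huToMu(hu)
  expect_true(all(diff(mu) >= 0))
})

test_that("CT reference map converts and complements missing coverage", {
  d <- c(3, 3, 3)
  ct <- array(0, d)
  ct[1, 1, 1] <- NaN   # unscanned, inside MRAC soft mask
  ct[2, 1, 1] <- NaN   # unscanned, outside mask
  ct[3, 3, 3] <- 500
  softMask <- array(0, d); softMask[1, 1, 1] <- 1
  ref <- ctReferenceMuMap(vg(ct), vg(softMask))
  expect_equal(ref@mu@data[1, 1, 1], 0.096)
  expect_equal(ref@mu@data[2, 1, 1], 0)
  expect_equal(ref@mu@data[3, 3, 3], huToMu(500))
  expect_equal(ref@mu@data[2, 2, 2], huToMu(0))
  # fully covered CT: complementation is a no-op
  ct2 <- array(100, d)
  ref2 <- ctReferenceMuMap(vg(ct2), vg(array(1, d)))
  expect_equal(ref2@mu@data, huToMu(ct2))
})

test_that("segmented attenuation maps take values from the class set", {
  s <- generateSubject(phantomSpec(shape = c(48L, 48L, 48L)), 1)
  m <- assignMu(classifyTissues(s@probmaps))
  co <- muCoefficients()
  expect_true(all(m@mu@data %in%
                    co[c("air", "soft", "brain", "bone")]))
})
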