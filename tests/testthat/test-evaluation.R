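test_that("dice handles identity, disjoint, partial overlap and emptiness", {
  d <- c(6, 6, 6)
  a <- array(0, d); a[1:2, 1:2, 1] <- 1
  b <- array(0, d); b[1:2, 1, 1] <- 1; b[3:4, 3, 3] <- 1
  expect_equal(dice(vg(a), vg(a)), 1)
  disj <- array(0, d); disj[5:6, 5:6, 5] <- 1
  expect_equal(dice(vg(a), vg(disj)), 0)
  expect_equal(dice(vg(a), vg(b)), 2 * 2 / (4 + 4))   # |A|=4,|B|=4,overlap 2
  expect_equal(dice(vg(array(0, d)), vg(array(0, d))), 1)
  expect_equal(dice(vg(array(0, d)), vg(array(0, d)), emptyValue = NA),
               NA)
  expect_equal(dice(vg(a), vg(b)), dice(vg(b), vg(a)))  # symmetric
})

test_that("bone masks threshold strictly at the boundary", {
  d <- c(3, 3, 3)
  ct <- array(c(157, 158, -1000, 200, 0, 156, 1000, NaN, 157), c(3, 3, 1))
  ct <- vg(array(ct, d))
  labels <- vg(array(tissueLabels()[["bone"]], d))
  mrac <- assignMu(labels)
  masks <- boneMasksForDice(ct, mrac)
  expect_equal(masks$ct@data[1, 1, 1], 0)   # exactly 157 excluded
  expect_equal(masks$ct@data[2, 1, 1], 1)
  expect_equal(masks$ct@data[2, 3, 1], 0)   # NaN coverage sentinel excluded
  expect_true(all(masks$mrac@data == 1))    # 0.151 > 0.105
  bulk <- applyBulkSinus(mrac, vg(array(1, d)))
  expect_true(all(boneMasksForDice(ct, bulk)$mrac@data == 0))  # 0.100 out
})

test_that("sinus sub-volume crops the configured axial window", {
  v <- vg(array(seq_len(8 * 8 * 96), c(8, 8, 96)), spacing = c(2, 2, 2))
  sub <- sinusSubvolume(v)
  expect_identical(dim(sub@data)[3], 21L)
  expect_equal(dim(sub@data)[3] * sub@spacing[3] / 10, 4.2)   # cm
  expect_identical(sub@data[, , 1], v@data[, , 50])
  one <- sinusSubvolume(v, c(7, 7))
  expect_identical(dim(one@data)[3], 1L)
  expect_error(sinusSubvolume(v, c(70, 50)), "increasing")
  expect_error(sinusSubvolume(v, c(1, 200)), "outside")
})

test_that("correlation sampling is seeded and reproduces exact identities", {
  set.seed(19)
  d <- c(12, 12, 12)
  ct <- array(runif(prod(d)), d)
  mask <- array(1, d)
  rsSame <- sampleCorrelations(vg(ct), vg(ct), vg(mask), nVox = 50,
                               nReps = 10, seed = 4)
  expect_true(all(abs(rsSame - 1) < 1e-12))
  rsNeg <- sampleCorrelations(vg(ct), vg(-ct + 2), vg(mask), nVox = 50,
                              nReps = 10, seed = 4)
  expect_true(all(abs(rsNeg + 1) < 1e-12))
  rsA <- sampleCorrelations(vg(ct), vg(ct + rnorm(prod(d))), vg(mask),
                            nVox = 50, nReps = 10, seed = 7)
  rsB <- sampleCorrelations(vg(ct), vg(ct + rnorm(prod(d))), vg(mask),
                            nVox = 50, nReps = 10, seed = 7)
  expect_true(all(rsA >= -1 & rsA <= 1))
  # zero variance records NA
  rsFlat <- sampleCorrelations(vg(ct), vg(array(1, d)), vg(mask),
                               nVox = 20, nReps = 3, seed = 1)
  expect_true(all(is.na(rsFlat)))
  expect_error(sampleCorrelations(vg(ct), vg(ct),
                                  vg(array(0, d)), nVox = 10),
               "fewer voxels")
})

test_that("correlation spread narrows as the draw size grows", {
  set.seed(29)
  d <- c(16, 16, 16)
  ct <- array(runif(prod(d)), d)
  mrac <- ct + array(rnorm(prod(d), sd = 0.4), d)
  mask <- array(1, d)
  iqrAt <- function(nv) {
    rs <- sampleCorrelations(vg(ct), vg(mrac), vg(mask), nVox = nv,
                             nReps = 60, seed = 2)
    IQR(rs)
  }
  expect_lt(iqrAt(400), iqrAt(40))
})

test_that("VOI mean attenuation averages the masked voxels", {
  d <- c(4, 4, 4)
  mu <- array(0.100, d)
  voi <- array(1, d)
  expect_equal(voiMeanMu(vg(mu), vg(voi)), 0.100)
  mu2 <- array(c(rep(0, 32), rep(0.096, 32)), d)
  expect_equal(voiMeanMu(vg(mu2), vg(voi)), 0.048)
  expect_error(voiMeanMu(vg(mu), vg(array(0, d))), "empty")
})

test_that("VOI relative differences follow the defining identity", {
  d <- c(6, 6, 6)
  set.seed(5)
  pet <- array(runif(prod(d), 1, 10), d)
  labels <- array(sample(0:3, prod(d), TRUE), d)
  gm <- array(runif(prod(d)), d)
  tab0 <- voiRelDiff(vg(pet), vg(pet), vg(labels), vg(gm))
  expect_true(all(tab0$relDiff == 0))
  tab5 <- voiRelDiff(vg(pet * 1.05), vg(pet), vg(labels), vg(gm))
  expect_equal(tab5$relDiff, rep(0.05, nrow(tab5)), tolerance = 1e-12)
  # exact linearity: scaling by (1 + eps) shifts every defined row by eps
  eps <- 0.123
  tabE <- voiRelDiff(vg(pet * (1 + eps)), vg(pet), vg(labels), vg(gm))
  expect_equal(tabE$relDiff, tab0$relDiff + eps, tolerance = 1e-12)
  # a VOI fully below the threshold is absent
  gm2 <- gm; gm2[labels == 2] <- 0
  tabA <- voiRelDiff(vg(pet), vg(pet), vg(labels), vg(gm2))
  expect_false(2 %in% tabA$voi)
  # zero reference records NA
  petZ <- pet; petZ[labels == 1 & gm >= 0.8] <- 0
  tabZ <- voiRelDiff(vg(pet), vg(petZ), vg(labels), vg(gm))
  expect_true(is.na(tabZ$relDiff[tabZ$voi == 1]))
})

test_that("bias atlas averages voxelwise relative differences", {
  d <- c(5, 5, 5)
  set.seed(6)
  ctac <- vg(array(runif(prod(d), 1, 5), d))
  brain <- array(0, d); brain[2:4, 2:4, 2:4] <- 1
  same <- biasAtlas(list(list(mrac = ctac, ctac = ctac)), vg(brain))
  expect_true(all(same@data[brain == 1] == 0))
  expect_true(all(is.na(same@data[brain == 0])))
  up <- withData(ctac, ctac@data * 1.1)
  down <- withData(ctac, ctac@data * 0.9)
  cancel <- biasAtlas(list(list(mrac = up, ctac = ctac),
                           list(mrac = down, ctac = ctac)), vg(brain))
  expect_equal(max(abs(cancel@data[brain == 1])), 0, tolerance = 1e-12)
  two <- biasAtlas(list(list(mrac = withData(ctac, ctac@data * 1.02),
                             ctac = ctac)), vg(brain))
  expect_equal(unique(round(two@data[brain == 1], 12)), 0.02)
  expect_error(biasAtlas(list(), vg(brain)), "empty")
})
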