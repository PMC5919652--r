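sch <- make199Scheme(1, 2.5)
vox <- c(0.25, 0.25, 0.5)

test_that("mask volumetry is exact integer arithmetic times a constant", {
  m <- array(FALSE, c(4, 4, 4))
  m[1:10] <- TRUE
  expect_equal(volumeFromMask(m, vox), 10 * 0.25 * 0.25 * 0.5 / 1000)
  expect_equal(volumeFromMask(m, vox), 3.125e-4)
  expect_equal(volumeFromMask(array(FALSE, c(2, 2, 2)), vox), 0)
  ## doubling the voxel edge octuples the volume for the same count
  expect_equal(volumeFromMask(m, 2 * vox), 8 * volumeFromMask(m, vox))
  expect_error(volumeFromMask(array(0.5, c(2, 2, 2)), vox), "binary")
})

test_that("mismatch percent reproduces the reported group-mean arithmetic", {
  expect_equal(round(mismatchPercent(0.304, 0.232), 1), 31.0)
  expect_equal(mismatchPercent(1, 1), 0)
  expect_equal(mismatchPercent(1.31, 1), 31, tolerance = 1e-12)
  expect_error(mismatchPercent(1, 0), "positive")
})

test_that("all-zero series yields fully flagged maps without error", {
  series <- array(0, c(3, 3, 3, 19))
  maps <- fitMaps(series, scheme = sch, voxelSize = vox)
  expect_true(all(mapFlags(maps$md) > 0))
  expect_true(all(is.na(mapValues(maps$md))))
  fl <- flagNames(mapFlags(maps$md)[1])[[1]]
  expect_true("NONPOSITIVE_SIGNAL" %in% fl)
})

test_that("voxels outside the mask carry sentinel and OUTSIDE_MASK", {
  truth <- defaultTruth()
  ser <- simulateAcquisition(truth, sch, snr = Inf)
  m <- phantomMasks(truth)
  maps <- fitMaps(ser, mask = m$brain)
  outside <- !m$brain
  expect_true(all(is.na(mapValues(maps$md)[outside])))
  expect_true(all(mapFlags(maps$md)[outside] == 16L))
  expect_true(all(mapFlags(maps$md)[m$brain] == 0L))
})

test_that("fitting is voxel-independent (permutation invariance)", {
  set.seed(123)
  series <- array(runif(4 * 3 * 2 * 19, 0.2, 1), c(4, 3, 2, 19))
  series[, , , 1] <- 1
  maps <- fitMaps(series, scheme = sch, voxelSize = vox)
  perm <- sample(4 * 3 * 2)
  S <- series; dim(S) <- c(24, 19)
  Sp <- S[perm, ]; dim(Sp) <- c(4, 3, 2, 19)
  mapsP <- fitMaps(Sp, scheme = sch, voxelSize = vox)
  v <- mapValues(maps$mkt); vp <- mapValues(mapsP$mkt)
  expect_equal(as.numeric(v)[perm], as.numeric(vp))
  vmd <- mapValues(maps$md); vmdp <- mapValues(mapsP$md)
  expect_equal(as.numeric(vmd)[perm], as.numeric(vmdp))
})

test_that("connected-component labeling separates and sizes blobs", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1:2, 1:2] <- TRUE          # 8 voxels
  m[5:6, 5:6, 5:6] <- TRUE          # 8 voxels, corner-separated
  lab <- labelComponents(m, 26)
  expect_equal(sort(attr(lab, "sizes")), c(8L, 8L))
  ## diagonal touch merges under 26- but not 6-connectivity
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(length(attr(labelComponents(m2, 26), "sizes")), 1L)
  expect_equal(length(attr(labelComponents(m2, 6), "sizes")), 2L)
  big <- largestComponent(m | (array(seq_len(216), dim(m)) == 100), 26)
  expect_lte(sum(big), 9)
})

test_that("hemisphere split partitions the bounding box at mid-plane", {
  truth <- defaultTruth()
  brain <- phantomMasks(truth)$brain
  h <- hemisphereMasks(brain)
  expect_equal(h$left | h$right, brain)
  expect_false(any(h$left & h$right))
  expect_identical(h$left, phantomMasks(truth)$left)
})

test_that("noiseless phantom segments exactly (Dice >= 0.99)", {
  truth <- defaultTruth()
  ser <- simulateAcquisition(truth, sch, snr = Inf)
  m <- phantomMasks(truth)
  maps <- fitMaps(ser, mask = m$brain)
  lesMD <- segmentLesion(maps$md, m$brain, m$left, "md_low", k = 2)
  lesMKT <- segmentLesion(maps$mkt, m$brain, m$left, "mkt_high", k = 2)
  expect_gte(diceCoef(lesMD, m$lesion_md), 0.99)
  expect_gte(diceCoef(lesMKT, m$lesion_mkt), 0.99)
  expect_equal(attr(lesMD, "provenance"), "threshold")
})

test_that("uniform maps give empty lesions; empty contralateral errors", {
  truth <- defaultTruth()
  ser <- simulateAcquisition(truth, sch, snr = Inf)
  m <- phantomMasks(truth)
  maps <- fitMaps(ser, mask = m$brain)
  ## restrict to the left hemisphere: uniform there, nothing below threshold
  uniform <- segmentLesion(maps$md, m$left, m$left, "md_low", k = 2)
  expect_equal(sum(uniform), 0)
  empty <- array(FALSE, dim(m$brain))
  expect_error(segmentLesion(maps$md, m$brain, empty, "md_low"), "usable")
})

test_that("raising k never grows the thresholded set", {
  truth <- defaultTruth()
  ser <- simulateAcquisition(truth, sch, snr = 50, seed = 11)
  m <- phantomMasks(truth)
  maps <- fitMaps(ser, mask = m$brain)
  sizes <- sapply(c(0.5, 1, 2, 3), function(k) {
    v <- mapValues(maps$mkt)
    usable <- is.finite(v) & mapFlags(maps$mkt) == 0
    ref <- v[m$left & usable]
    thr <- mean(ref) + k * sd(ref)
    sum(m$brain & usable & v > thr)   # pre-component-selection count
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("MD lesion volume is recovered within 10% at SNR 50", {
  truth <- defaultTruth()
  m <- phantomMasks(truth)
  vTrue <- volumeFromMask(m$lesion_md, vox)
  vols <- sapply(1:5, function(seed) {
    ser <- simulateAcquisition(truth, sch, snr = 50, seed = seed)
    maps <- fitMaps(ser, mask = m$brain)
    les <- segmentLesion(maps$md, m$brain, m$left, "md_low", k = 2)
    volumeFromMask(les, vox)
  })
  expect_lt(abs(mean(vols) - vTrue) / vTrue, 0.10)
})
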