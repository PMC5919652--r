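test_that("systematic sampling picks every 1/ssf-th section", {
  m <- array(TRUE, c(2, 2, 30))
  st <- sliceSections(m, 500, c(1, 1, 0.5))   # 30 sections
  sub <- systematicSample(st, 1 / 15, 0)
  expect_length(sections(sub), 2)             # sections 1 and 16
  expect_identical(sections(systematicSample(st, 1, 0)), sections(st))
  expect_error(systematicSample(st, 1 / 15, 15), "start")
  expect_error(systematicSample(st, 0.3, 0), "whole number")
  ## 375 sections at ssf 1/15 -> 25 kept for every start offset
  st375 <- sliceSections(array(TRUE, c(2, 2, 30)), 40, c(1, 1, 0.5))
  counts <- sapply(0:14, function(s)
    length(sections(systematicSample(st375, 1 / 15, s))))
  expect_true(all(counts == 25))
})

test_that("point counting is exact on grid-aligned rectangles and unbiased on disks", {
  px <- 0.1
  sec <- matrix(FALSE, 100, 100)       # 10 x 10 mm section
  sec[21:60, 31:50] <- TRUE            # 4 x 2 mm rectangle
  a <- pointCountArea(sec, d = 0.5, offset = c(0, 0), pixelSize = c(px, px))
  expect_equal(as.numeric(a), 8)       # half-open convention: exactly a*b
  expect_equal(as.numeric(pointCountArea(matrix(FALSE, 10, 10), 0.5,
                                         pixelSize = c(px, px))), 0)
  ## disk of radius 3 mm: systematic grids are unbiased over random offsets
  cc <- ((1:120) - 0.5) * px
  disk <- outer(cc, cc, function(x, y) (x - 6)^2 + (y - 6)^2 <= 9)
  set.seed(4)
  ests <- replicate(100, as.numeric(
    pointCountArea(disk, 0.1, offset = runif(2, 0, 0.1),
                   pixelSize = c(px, px))))
  expect_lt(abs(mean(ests) - pi * 9) / (pi * 9), 0.01)
})

test_that("nucleator recovers disk and square areas and flags crescents", {
  ## fine raster so the raster-boundary error stays below the 0.1% claim
  pxf <- 0.0025
  ccf <- ((1:2560) - 0.5) * pxf
  diskF <- outer(ccf, ccf, function(x, y) (x - 3.2)^2 + (y - 3.2)^2 <= 4)
  a <- nucleatorArea(diskF, c(3.2, 3.2), nRays = 64,
                     pixelSize = c(pxf, pxf), seed = 1)
  expect_lt(abs(as.numeric(a) - pi * 4) / (pi * 4), 0.001)
  expect_false(attr(a, "NON_STAR_SHAPED"))
  px <- 0.01
  cc <- ((1:640) - 0.5) * px
  disk <- outer(cc, cc, function(x, y) (x - 3.2)^2 + (y - 3.2)^2 <= 4)
  ## square side 2: expectation over rotations equals the area
  sq <- outer(cc, cc, function(x, y) abs(x - 3.2) <= 1 & abs(y - 3.2) <= 1)
  set.seed(8)
  ests <- replicate(200, as.numeric(
    nucleatorArea(sq, c(3.2, 3.2), nRays = 8, pixelSize = c(px, px))))
  expect_lt(abs(mean(ests) - 4) / 4, 0.01)
  ## crescent: disk minus off-center disk; rays re-enter
  crescent <- disk & !outer(cc, cc, function(x, y)
    (x - 4.2)^2 + (y - 3.2)^2 <= 2.25)
  ref <- c(2.2, 3.2)
  expect_true(crescent[floor(ref[1] / px) + 1, floor(ref[2] / px) + 1])
  ac <- nucleatorArea(crescent, ref, nRays = 64, pixelSize = c(px, px),
                      seed = 2)
  expect_true(attr(ac, "NON_STAR_SHAPED"))
  expect_error(nucleatorArea(disk, c(0.01, 0.01), pixelSize = c(px, px)),
               "inside")
})

test_that("nucleator and point counting agree on convex sections", {
  px <- 0.01
  cc <- ((1:640) - 0.5) * px
  disk <- outer(cc, cc, function(x, y)
    ((x - 3.2) / 2)^2 + ((y - 3.2) / 1.4)^2 <= 1)   # ellipse 2 x 1.4 mm
  set.seed(12)
  aN <- mean(replicate(20, as.numeric(
    nucleatorArea(disk, c(3.2, 3.2), nRays = 64, pixelSize = c(px, px)))))
  aP <- as.numeric(pointCountArea(disk, 0.05, offset = c(0.01, 0.02),
                                  pixelSize = c(px, px)))
  expect_lt(abs(aN - aP) / aP, 0.02)
})

test_that("Cavalieri volume arithmetic and unit conversion are exact", {
  est <- cavalieriVolume(c(1, 2, 3), 40, 1 / 15)
  expect_equal(cavalieriEstimateVolume(est), 3.6e-3)
  expect_equal(cavalieriEstimateVolume(cavalieriVolume(5, 100, 1)),
               100 * 5 * 1e-6)          # single section, ssf = 1 -> t*a
  expect_error(cavalieriVolume(numeric(0), 40, 1 / 15), "nonempty")
  ## linearity in the areas
  e1 <- cavalieriVolume(c(1, 2), 40, 1 / 15)
  e2 <- cavalieriVolume(3 * c(1, 2), 40, 1 / 15)
  expect_equal(cavalieriEstimateVolume(e2), 3 * cavalieriEstimateVolume(e1))
})

test_that("averaging over all start offsets removes the sampling error", {
  m <- phantomMasks(defaultTruth())$lesion_mkt
  st <- sliceSections(m, 40, c(0.25, 0.25, 0.5))
  areas <- vapply(sections(st), sectionArea, 0, pixelSize = c(0.25, 0.25))
  stackVol <- sum(areas) * 40 * 1e-6          # full-stack Riemann volume
  ests <- sapply(0:14, function(s) {
    sub <- systematicSample(st, 1 / 15, s)
    a <- vapply(sections(sub), sectionArea, 0, pixelSize = c(0.25, 0.25))
    cavalieriEstimateVolume(cavalieriVolume(a, 40, 1 / 15, start = s))
  })
  ## algebraic identity: every section counted once across offsets
  expect_equal(mean(ests), stackVol, tolerance = 1e-12)
  ## and the stack volume approximates the voxel mask volume
  expect_lt(abs(stackVol - volumeFromMask(m, c(0.25, 0.25, 0.5))) /
            volumeFromMask(m, c(0.25, 0.25, 0.5)), 0.02)
  ## single-offset estimates fluctuate around the mean
  expect_gt(stats::sd(ests), 0)
})
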