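sch <- make199Scheme(1, 2.5)

test_that("predictSignal evaluates the two-term cumulant model", {
  D <- diffusionTensor(0.5)
  expect_equal(predictSignal(2, 0, c(1, 0, 0), D), 2)            # b = 0
  expect_equal(predictSignal(1, 2, c(0, 0, 1), D), exp(-1))      # W = 0
  W <- isotropicKurtosisTensor(1)
  ## -b*MD + b^2/6 * MD^2 * MKT = -0.5 + 0.25/6
  expect_equal(log(predictSignal(1, 1, c(1, 0, 0), D, W)),
               -0.5 + 0.25 / 6)
  expect_equal(log(predictSignal(1, 1, c(0, 1, 0), D, W)), -0.458333333,
               tolerance = 1e-8)
  expect_error(predictSignal(0, 1, c(1, 0, 0), D), "positive")
  expect_error(predictSignal(-1, 1, c(1, 0, 0), D), "positive")
})

test_that("log-sum average reduces the directional model to scalars", {
  D <- diffusionTensor(0.5)
  W <- isotropicKurtosisTensor(1)
  dirs <- schemeDirections(sch)
  s1 <- apply(dirs, 1, function(n) predictSignal(1, 1, n, D, W))
  expect_equal(as.numeric(logSumAverage(s1, 1, sch)), -0.458333333,
               tolerance = 1e-9)
  ## anisotropic Gaussian: reduces to -b * Tr(D)/3
  Da <- diffusionTensor(diag(c(1.5, 0.3, 0.3)))
  sa <- apply(dirs, 1, function(n) predictSignal(1, 1, n, Da))
  expect_equal(as.numeric(logSumAverage(sa, 1, sch)), -0.7,
               tolerance = 1e-12)
  ## all signals equal to s0 average to zero
  expect_equal(as.numeric(logSumAverage(rep(3, 9), 3, sch)), 0)
  ## clamping marks the result
  out <- logSumAverage(c(rep(1, 8), 0), 1, sch)
  expect_true(attr(out, "clamped"))
})

test_that("closed-form MD and MKT invert the two-equation system", {
  expect_equal(estimateMD199(-0.5, -1.25, 1, 2.5), 0.5)
  expect_equal(estimateMD199(0, 0, 1, 2.5), 0)
  expect_equal(estimateMD199(-0.458333333333, -0.989583333333, 1, 2.5),
               0.5, tolerance = 1e-9)
  ## Gaussian decay (A linear in b) has zero kurtosis
  expect_equal(as.numeric(estimateMKT199(-0.5, -1.25, 1, 2.5)), 0)
  expect_equal(as.numeric(
    estimateMKT199(-0.458333333333, -0.989583333333, 1, 2.5)),
    1, tolerance = 1e-8)
  z <- estimateMKT199(0, 0, 1, 2.5)
  expect_true(attr(z, "degenerate"))
  expect_true(is.na(as.numeric(z)))
  expect_error(estimateMD199(-0.5, -1.25, 1, 1), "distinct")
})

test_that("estimateVoxel round-trips noiseless phantom voxels", {
  D <- diffusionTensor(0.5)
  W <- isotropicKurtosisTensor(1)
  est <- estimateVoxel(noiselessSignals(sch, D, W), sch)
  expect_equal(est$md, 0.5, tolerance = 1e-12)
  expect_equal(est$mkt, 1, tolerance = 1e-10)
  expect_length(est$flags, 0)
  ## all 19 signals equal: zero decay
  est <- estimateVoxel(rep(2, 19), sch)
  expect_equal(est$md, 0)
  expect_true("DEGENERATE_DENOMINATOR" %in% est$flags)
  ## dead b = 0 voxel: flagged, never throws
  est <- estimateVoxel(rep(0, 19), sch)
  expect_true(all(c("NONPOSITIVE_SIGNAL", "DEGENERATE_DENOMINATOR") %in%
                  est$flags))
})

test_that("exact inversion holds for random anisotropic (D, W) pairs", {
  set.seed(2024)
  worstMD <- worstMKT <- 0
  for (rep in 1:200) {
    D <- randomPSD()
    rw <- randomSymmetricW()
    Wbar <- mktTrace(rw$W)
    W <- if (abs(Wbar) > 3) {
      kurtosisTensor(tensorArray(rw$W) * 3 / abs(Wbar))
    } else rw$W
    est <- estimateVoxel(noiselessSignals(sch, D, W), sch,
                         dkiConfig(mdRange = c(-10, 10),
                                   mktRange = c(-10, 10)))
    worstMD <- max(worstMD, abs(est$md - meanDiffusivity(D)))
    worstMKT <- max(worstMKT, abs(est$mkt - mktTrace(W)))
  }
  expect_lt(worstMD, 1e-10)
  expect_lt(worstMKT, 1e-8)
})

test_that("b-scaling leaves MKT invariant and scales MD by 1/c", {
  set.seed(9)
  D <- randomPSD()
  rw <- randomSymmetricW()
  c0 <- 2.0
  base <- estimateVoxel(noiselessSignals(sch, D, rw$W), sch,
                        dkiConfig(mdRange = c(-10, 10),
                                  mktRange = c(-10, 10)))
  ## scale b by c and D by 1/c: log-signal is preserved volume by volume
  sch2 <- make199Scheme(1 * c0, 2.5 * c0)
  D2 <- diffusionTensor(tensorArray(D) / c0)
  scaled <- estimateVoxel(noiselessSignals(sch2, D2, rw$W), sch2,
                          dkiConfig(mdRange = c(-10, 10),
                                    mktRange = c(-10, 10)))
  expect_equal(scaled$md, base$md / c0, tolerance = 1e-10)
  expect_equal(scaled$mkt, base$mkt, tolerance = 1e-8)
})

test_that("estimator RMSE shrinks monotonically with SNR", {
  D <- diffusionTensor(0.5)
  W <- isotropicKurtosisTensor(0.8)
  clean <- noiselessSignals(sch, D, W)
  snrs <- c(10, 25, 50, 100)
  nrep <- 400
  set.seed(77)
  rmse <- sapply(snrs, function(snr) {
    sigma <- 1 / snr
    errs <- replicate(nrep, {
      noisy <- sqrt((clean + rnorm(19, 0, sigma))^2 + rnorm(19, 0, sigma)^2)
      est <- estimateVoxel(noisy, sch)
      if (length(est$flags)) c(NA, NA) else
        c(est$md - 0.5, est$mkt - 0.8)
    })
    sqrt(rowMeans(errs^2, na.rm = TRUE))
  })
  expect_true(all(diff(rmse[1, ]) < 0))  # MD
  expect_true(all(diff(rmse[2, ]) < 0))  # MKT
})
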