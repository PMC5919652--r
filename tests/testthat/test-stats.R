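test_that("Shapiro-Wilk wrapper validates input and detects non-normality", {
  expect_error(shapiroWilk(c(1, 2)), "3 <= n")
  expect_error(shapiroWilk(rep(1, 10)), "variance")
  set.seed(1)
  bimodal <- c(rnorm(25, 0, 0.01), rnorm(25, 10, 0.01))
  expect_lt(shapiroWilk(bimodal)$p.value, 0.01)
  normal <- rnorm(50)
  res <- shapiroWilk(normal)
  expect_true(res$statistic > 0 && res$statistic <= 1)
})

test_that("paired t matches hand computation and the reference routine", {
  res <- pairedT(c(2, 3, 4), c(1, 1, 1))   # d = (1, 2, 3)
  expect_equal(unname(res$statistic), 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(unname(res$parameter), 2)
  ## cross-check statistic and p against stats::t.test
  set.seed(2)
  x <- rnorm(7, 1.4, 0.2); y <- rnorm(7, 1.45, 0.2)
  ref <- t.test(x, y, paired = TRUE)
  res <- pairedT(x, y)
  expect_equal(unname(res$statistic), unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
  expect_equal(unname(res$parameter), 6)   # n = 7 reporting convention
})

test_that("paired t handles degenerate differences by convention", {
  res <- pairedT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  res <- pairedT(c(2, 3, 4), c(1, 2, 3))
  expect_equal(unname(res$statistic), Inf)
  expect_equal(res$p.value, 0)
  expect_error(pairedT(1, numeric(0)), "equal length")
})

test_that("paired t is antisymmetric in its arguments", {
  set.seed(3)
  x <- rnorm(9); y <- rnorm(9)
  a <- pairedT(x, y); b <- pairedT(y, x)
  expect_equal(unname(a$statistic), -unname(b$statistic))
  expect_equal(a$p.value, b$p.value)
})

test_that("one-way ANOVA matches the brute-force decomposition and t^2", {
  g <- list(c(1, 2, 3, 2), c(2, 4, 3, 5), c(5, 6, 4, 7))
  res <- anovaOneway(g)
  ## explicit sum-of-squares oracle
  v <- unlist(g); gm <- mean(v)
  ssb <- sum(sapply(g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(sapply(g, function(x) sum((x - mean(x))^2)))
  Fo <- (ssb / 2) / (ssw / (length(v) - 3))
  expect_equal(unname(res$statistic), Fo, tolerance = 1e-12)
  expect_equal(unname(res$parameter), c(2, length(v) - 3))
  ## identical groups: F = 0, p = 1
  res0 <- anovaOneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)
  ## two groups: F equals the square of the pooled two-sample t
  x <- c(1.2, 1.9, 2.4, 3.1); y <- c(2.2, 2.8, 3.9)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(unname(anovaOneway(list(x, y))$statistic),
               unname(tt$statistic)^2, tolerance = 1e-12)
  expect_error(anovaOneway(list(1, 2)), "two observations")
  expect_error(anovaOneway(list(rep(1, 3), rep(1, 3))), "degenerate")
})

test_that("absolute-agreement ICC matches the sum-of-squares oracle", {
  set.seed(6)
  for (rep in 1:5) {
    m <- matrix(rnorm(12, 10, 2), 6, 2)
    res <- iccAbsoluteAgreement(m)
    expect_equal(res$icc, bruteTwoWayICC(m), tolerance = 1e-12)
  }
})

test_that("ICC is 1 for identical raters and penalizes constant offsets", {
  m <- cbind(c(9, 7, 5, 3), c(9, 7, 5, 3))
  res <- iccAbsoluteAgreement(m)
  expect_equal(res$icc, 1)
  off <- cbind(c(9, 7, 5, 3), c(9, 7, 5, 3) + 2)
  resOff <- iccAbsoluteAgreement(off)
  expect_lt(resOff$icc, 1)
  ## a consistency-type coefficient would be 1 here; absolute agreement is not
  expect_gt(resOff$icc, 0)
  ## shifting the whole table leaves ICC unchanged
  resShift <- iccAbsoluteAgreement(off + 5)
  expect_equal(resShift$icc, resOff$icc, tolerance = 1e-12)
  ## adding a constant to one rater strictly decreases ICC further
  worse <- cbind(off[, 1], off[, 2] + 2)
  expect_lt(iccAbsoluteAgreement(worse)$icc, resOff$icc)
  expect_error(iccAbsoluteAgreement(cbind(c(1, NA), c(1, 2))), "complete")
})

test_that("average-measure ICC exceeds single-measure on noisy tables", {
  set.seed(10)
  subj <- rnorm(8, 10, 3)
  m <- cbind(subj + rnorm(8, 0, 1), subj + rnorm(8, 0, 1),
             subj + rnorm(8, 0, 1))
  s <- iccAbsoluteAgreement(m, "single")
  a <- iccAbsoluteAgreement(m, "average")
  expect_gt(a$icc, s$icc)
  expect_true(s$lower < s$icc && s$icc < s$upper)
})

test_that("buildReport reproduces means, tests, mismatch and exclusions", {
  subjects <- paste0("r", 1:7)
  set.seed(21)
  md <- round(rnorm(7, 0.232, 0.02), 4)
  histo <- md  # designed equality: paired p = 1
  mkt <- round(1.31 * md, 6)
  volumes <- rbind(
    data.frame(subject = subjects, method = "MD", volume_cm3 = md),
    data.frame(subject = subjects, method = "histology", volume_cm3 = histo),
    data.frame(subject = subjects, method = "MKT", volume_cm3 = mkt))
  rep <- buildReport(volumes)
  ## spreadsheet arithmetic on the raw table
  expect_equal(rep$summary$mean_cm3[rep$summary$method == "MD"], mean(md))
  expect_equal(rep$summary$sd_cm3[rep$summary$method == "MKT"], sd(mkt))
  t_md_h <- rep$tests[rep$tests$method1 == "MD" &
                      rep$tests$method2 == "histology", ]
  expect_equal(t_md_h$p, 1)
  expect_equal(rep$mismatchPercent, 31, tolerance = 1e-9)
  ## listwise exclusion mirrors dropping subjects with failed histology
  volumes2 <- volumes[!(volumes$subject %in% c("r2", "r5") &
                        volumes$method == "histology"), ]
  expect_warning(rep2 <- buildReport(volumes2), "r2, r5")
  expect_equal(sort(rep2$excluded), c("r2", "r5"))
  expect_equal(rep2$summary$n[1], 5)
  expect_equal(unname(rep2$tests$df[1]), 4)
})

test_that("buildReport computes ICC tables from repeated ratings", {
  subjects <- paste0("r", 1:4)
  base <- c(0.2, 0.25, 0.3, 0.22)
  volumes <- do.call(rbind, lapply(1:2, function(rater)
    data.frame(subject = subjects, method = "MD",
               volume_cm3 = base + (rater - 1) * 0.001, rater = rater,
               check.names = FALSE)))
  rep <- buildReport(volumes)
  expect_false(is.null(rep$icc))
  expect_gt(rep$icc$MD$icc, 0.9)
  ## report files round-trip
  dir <- tempfile()
  paths <- writeReport(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(back$mean_cm3, rep$summary$mean_cm3, tolerance = 1e-12)
})
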