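test_that("icc31 handles the canonical hand-worked cases", {
  perfect <- icc31(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(perfect$icc, 1)
  expect_equal(c(perfect$ciLow, perfect$ciHigh), c(1, 1))

  # consistency form: a constant session shift is still perfect agreement
  shifted <- icc31(rbind(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(shifted$icc, 1)

  hand <- icc31(rbind(c(1, 2), c(2, 4), c(3, 6)))
  expect_equal(hand$msr, 4.5)
  expect_equal(hand$mse, 0.5)
  expect_equal(hand$icc, 0.8)

  expect_error(icc31(matrix(2, 3, 2)), "constant")
  expect_error(icc31(rbind(c(1, NA), c(2, 3))), "complete")
  expect_error(icc31(matrix(1:4, 1)), "at least 2")
})

test_that("icc31 equals the brute-force ANOVA oracle on random matrices", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(3:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, sd = sample(1:5, 1)), n, k) +
      rnorm(n)  # subject effects
    got <- icc31(m)
    want <- oracleICC31(m)
    expect_equal(got$icc, want$icc, tolerance = 1e-10)
    expect_equal(got$msr, want$msr, tolerance = 1e-10)
    expect_equal(got$mse, want$mse, tolerance = 1e-10)
    expect_equal(got$ciLow, want$ciLow, tolerance = 1e-10)
    expect_equal(got$ciHigh, want$ciHigh, tolerance = 1e-10)
    expect_true(got$ciLow <= got$icc && got$icc <= got$ciHigh)
    # invariance to adding a constant to one session's column
    m2 <- m; m2[, 1] <- m2[, 1] + 7
    expect_equal(icc31(m2)$icc, got$icc, tolerance = 1e-10)
  }
})

test_that("blandAltman reproduces hand-computed limits of agreement", {
  ba <- blandAltman(c(10, 30, 50), c(20, 10, 40))
  expect_equal(ba$meanDiff, 20 / 3, tolerance = 1e-12)
  expect_equal(ba$sdDiff, sd(c(-10, 20, 10)), tolerance = 1e-12)
  expect_equal(ba$loaLow, 20 / 3 - 1.96 * ba$sdDiff)
  expect_equal(ba$loaHigh, 20 / 3 + 1.96 * ba$sdDiff)
  expect_equal(round(c(ba$loaLow, ba$loaHigh), 2), c(-23.27, 36.61))

  same <- blandAltman(c(100, 200), c(100, 200))
  expect_equal(c(same$meanDiff, same$sdDiff, same$loaLow, same$loaHigh),
               c(0, 0, 0, 0))

  # antisymmetry under swapping the pair order
  swap <- blandAltman(c(20, 10, 40), c(10, 30, 50))
  expect_equal(swap$meanDiff, -ba$meanDiff)
  expect_equal(swap$loaLow, -ba$loaHigh)
  expect_equal(swap$loaHigh, -ba$loaLow)

  pc <- blandAltman(c(110, 90), c(90, 110), mode = "percent")
  expect_equal(pc$points$diff, c(20, -20))
  expect_error(blandAltman(c(1, -1), c(1, 1), mode = "percent"), "zero mean")
  expect_error(blandAltman(1, numeric(0)), "equal length")
  expect_s3_class(plotBlandAltman(ba), "ggplot")
})

test_that("summary t test matches t.test on raw data with exact moments", {
  exactSample <- function(n, m, s) {
    z <- as.vector(scale(rnorm(n)))
    m + s * z
  }
  set.seed(55)
  for (rep in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
    s1 <- runif(1, 0.5, 4); s2 <- runif(1, 0.5, 4)
    x <- exactSample(n1, m1, s1); y <- exactSample(n2, m2, s2)
    pooled <- tTestFromSummary(m1, s1, n1, m2, s2, n2, "pooled")
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(pooled$p, ref$p.value, tolerance = 1e-8)
    welch <- tTestFromSummary(m1, s1, n1, m2, s2, n2, "welch")
    refw <- t.test(x, y)
    expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-8)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-6)
    expect_equal(welch$p, refw$p.value, tolerance = 1e-8)
  }
  # identical groups -> t 0, p 1
  id <- tTestFromSummary(3, 1, 10, 3, 1, 10)
  expect_equal(c(id$t, id$p), c(0, 1))
  # frozen worked case
  tt <- tTestFromSummary(1, 1, 10, 2, 1, 10, "pooled")
  expect_equal(tt$t, -2.236, tolerance = 1e-3)
  expect_identical(tt$df, 18)
  expect_equal(tt$p, 0.0384, tolerance = 1e-2)
  expect_error(tTestFromSummary(1, 0, 10, 2, 0, 10), "not both zero")
  expect_error(tTestFromSummary(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("uncorrected Pearson chi-square matches direct summation", {
  sex <- rbind(c(32, 20), c(34, 17))  # women/men by study arm
  res <- chiSquareCounts(sex)
  expect_equal(res$statistic, 0.294, tolerance = 1e-2)
  expect_identical(formatP(res$p), ".59")
  expect_equal(res$df, 1)

  flat <- rbind(c(10, 20), c(20, 40))  # identical row proportions
  res0 <- chiSquareCounts(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  set.seed(9)
  tab <- matrix(rpois(6, 20), 2, 3)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chiSquareCounts(tab)$statistic, sum((tab - e)^2 / e),
               tolerance = 1e-12)
  expect_error(chiSquareCounts(rbind(c(1, 0), c(0, 0))), "2 x 2")
  expect_error(chiSquareCounts(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("ICC sample size inverts the expected CI width", {
  expect_identical(iccSampleSize(rho = 0.95, k = 2, width = 0.1), 15L)
  expect_identical(iccSampleSize(rho = 0.92, k = 2, width = 0.1), 37L)
  expect_identical(iccSampleSize(rho = 0.9999, k = 2, width = 0.1), 2L)
  # inverse consistency: w(n) <= width < w(n - 1)
  set.seed(3)
  for (rep in 1:25) {
    rho <- runif(1, 0.3, 0.99); k <- sample(2:4, 1)
    width <- runif(1, 0.02, 0.4)
    n <- iccSampleSize(rho, k, width)
    expect_lte(iccCIWidth(n, rho, k), width)
    if (n > 2L) expect_gt(iccCIWidth(n - 1L, rho, k), width)
  }
  expect_error(iccSampleSize(1.2), "rho")
  expect_error(iccSampleSize(0.9, width = 0), "width")
})

test_that("p values are formatted in reporting style", {
  expect_identical(formatP(c(0.0032, 0.0161, 0.837)),
                   c(".003", ".02", ".84"))
  expect_identical(formatP(0.0005), "<.001")
  expect_identical(formatP(1), "1.00")
})
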