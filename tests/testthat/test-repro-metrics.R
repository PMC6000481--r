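test_that("extent counts drawn pixels inside the outline", {
  os <- fullOutlines(c(12, 10))
  m <- matrix(0L, 12, 10); m[3:7, 2:5] <- 4L  # 5 x 4 rectangle
  expect_identical(symptomExtent(symptomMap("front", m), os), 20L)
  expect_identical(symptomExtent(blankMap("front", c(12, 10)), os), 0L)
  set.seed(5)
  for (rep in 1:20) {
    v <- randomVasMatrix(9, 11, 0.3)
    expect_identical(symptomExtent(symptomMap("back", v)),
                     sum(sapply(seq_along(v), function(i) v[i] > 0L)))
  }
})

test_that("cluster counting matches flood-fill oracle at both connectivities", {
  # one disk -> 1; two separated disks -> 2
  m <- matrix(FALSE, 20, 20)
  for (r in 1:20) for (c in 1:20) {
    if ((r - 5)^2 + (c - 5)^2 <= 9) m[r, c] <- TRUE
    if ((r - 14)^2 + (c - 14)^2 <= 9) m[r, c] <- TRUE
  }
  expect_identical(clusterCount(m), 2L)
  # diagonal touch: joined under 8-connectivity, split under 4
  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_identical(clusterCount(d, 8), 1L)
  expect_identical(clusterCount(d, 4), 2L)
  expect_identical(oracleClusterCount(d, 8), 1L)
  expect_identical(oracleClusterCount(d, 4), 2L)
  set.seed(17)
  for (rep in 1:30) {
    mask <- randomMask(12, 12, runif(1, 0.1, 0.5))
    for (conn in c(4, 8))
      expect_identical(clusterCount(mask, conn),
                       oracleClusterCount(mask, conn))
  }
  expect_error(clusterCount(m, 6), "connectivity")
})

test_that("overlap statistics match pixel enumeration", {
  sq <- matrix(FALSE, 8, 8); sq[3:5, 3:5] <- TRUE
  shifted <- matrix(FALSE, 8, 8); shifted[3:5, 4:6] <- TRUE
  ov <- overlapStats(sq * 1L, shifted * 1L)
  expect_identical(ov$intersection, 6L)
  expect_identical(ov$union, 12L)
  expect_identical(ov$jaccard, 0.5)

  same <- overlapStats(sq * 3L, sq * 7L)
  expect_identical(same$jaccard, 1)
  disjoint <- matrix(FALSE, 8, 8); disjoint[7:8, 7:8] <- TRUE
  expect_identical(overlapStats(sq * 1L, disjoint * 1L)$jaccard, 0)
  # undefined stays NA
  z <- matrix(0L, 8, 8)
  expect_true(is.na(overlapStats(z, z)$jaccard))

  set.seed(23)
  for (rep in 1:25) {
    a <- randomMask(10, 7, 0.3); b <- randomMask(10, 7, 0.3)
    got <- overlapStats(a * 1L, b * 1L)
    want <- oracleOverlap(a, b)
    expect_identical(got$intersection, want$intersection)
    expect_identical(got$union, want$union)
    expect_equal(got$jaccard, want$jaccard)
    # symmetry
    rev <- overlapStats(b * 1L, a * 1L)
    expect_identical(rev$intersection, got$intersection)
    expect_identical(rev$union, got$union)
  }
})

test_that("extent and clusters obey the set-theoretic bounds", {
  set.seed(41)
  for (rep in 1:20) {
    a <- randomVasMatrix(10, 10, 0.25)
    b <- randomVasMatrix(10, 10, 0.25)
    ma <- symptomMap("front", a); mb <- symptomMap("front", b)
    merged <- mergeSymptomMaps(list(ma, mb))
    ea <- symptomExtent(ma); eb <- symptomExtent(mb)
    em <- symptomExtent(merged)
    expect_lte(em, ea + eb)
    disjoint <- !any(a > 0L & b > 0L)
    expect_identical(em == ea + eb, disjoint)
    expect_lte(clusterCount(merged), em)
    # adding ink never decreases extent
    more <- a; more[1, 1] <- 10L
    expect_gte(symptomExtent(symptomMap("front", more)), ea)
  }
})

test_that("analyzePair reproduces hand-enumerated view metrics", {
  os <- fullOutlines(c(16, 12))
  sq <- matrix(0L, 16, 12); sq[4:6, 4:6] <- 5L           # 3x3 square
  sh <- matrix(0L, 16, 12); sh[4:6, 5:7] <- 5L           # shifted 1 col
  two <- matrix(0L, 16, 12); two[2, 2] <- 1L; two[10, 10] <- 2L
  test <- drawingFromMats(list(front = sq, back = two), os,
                          session = "test")
  retest <- drawingFromMats(list(front = sh, back = two), os,
                            session = "retest")
  res <- analyzePair(test, retest)
  front <- res$views[res$views$view == "front", ]
  expect_identical(front$extent1, 9L)
  expect_identical(front$extent2, 9L)
  expect_identical(front$intersection, 6L)
  expect_identical(front$union, 12L)
  expect_equal(front$jaccard, 0.5)
  expect_identical(front$clusters1, 1L)
  back <- res$views[res$views$view == "back", ]
  expect_identical(back$clusters1, 2L)
  expect_equal(back$jaccard, 1)
  # whole drawing pools pixels over included views
  expect_identical(res$whole$extent1, 9L + 2L)
  expect_equal(res$whole$jaccard, (6 + 2) / (12 + 2))
  expect_equal(res$aggregates$jaccardMax, 1)
  expect_equal(res$aggregates$jaccardMean, 0.75)
  # left/right blank in both sessions: excluded, whole metrics unaffected
  expect_identical(res$views$included, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("a view drawn in one session only stays in with Jaccard 0", {
  os <- fullOutlines(c(10, 10))
  only1 <- matrix(0L, 10, 10); only1[2:3, 2:3] <- 5L
  test <- drawingFromMats(list(left = only1), os, session = "test")
  retest <- drawingFromMats(list(), os, session = "retest")
  res <- analyzePair(test, retest)
  left <- res$views[res$views$view == "left", ]
  expect_true(left$included)
  expect_equal(left$jaccard, 0)
  resEither <- analyzePair(test, retest, excludeWhen = "either")
  expect_false(resEither$views$included[resEither$views$view == "left"])
})

test_that("identical drawings give Jaccard 1 everywhere drawn", {
  set.seed(12)
  os <- fullOutlines(c(14, 14))
  mats <- list(front = randomVasMatrix(14, 14, 0.3),
               right = randomVasMatrix(14, 14, 0.2))
  a <- drawingFromMats(mats, os, session = "test")
  b <- drawingFromMats(mats, os, session = "retest")
  res <- analyzePair(a, b)
  inc <- res$views[res$views$included, ]
  expect_true(all(inc$jaccard == 1))
  expect_identical(inc$extent1, inc$extent2)
  expect_equal(res$whole$jaccard, 1)
})

test_that("analyzePair rejects mismatched patients or outlines", {
  os <- fullOutlines(c(10, 10))
  a <- makeBlankDrawing(os, "P1", "test")
  b <- makeBlankDrawing(os, "P2", "retest")
  expect_error(analyzePair(a, b), "different patients")
  os2 <- fullOutlines(c(12, 10))
  expect_error(analyzePair(a, makeBlankDrawing(os2, "P1", "retest")),
               "outline")
})

test_that("cohortSummary aggregates pairs and matches the ANOVA oracle", {
  os <- fullOutlines(c(20, 20))
  # hand-set extents: patient i draws an i-dependent square, identical twice
  mk <- function(side, session) {
    m <- matrix(0L, 20, 20); m[seq_len(side), seq_len(side)] <- 5L
    drawingFromMats(list(front = m), os, patientId = paste0("P", side),
                    session = session)
  }
  results <- lapply(c(3, 5, 8, 11), function(s)
    analyzePair(mk(s, "test"), mk(s, "retest")))
  s <- cohortSummary(results)
  expect_equal(s$jaccardMean, 1)
  whole <- s$icc[s$icc$scope == "whole" & s$icc$metric == "extent", ]
  expect_equal(whole$icc, 1)

  # cohort with within-pair differences: ICC equals the brute-force value
  mk2 <- function(s1, s2, id) {
    m1 <- matrix(0L, 20, 20); m1[seq_len(s1), seq_len(s1)] <- 5L
    m2 <- matrix(0L, 20, 20); m2[seq_len(s2), seq_len(s2)] <- 5L
    analyzePair(
      drawingFromMats(list(front = m1), os, patientId = id, session = "test"),
      drawingFromMats(list(front = m2), os, patientId = id,
                      session = "retest"))
  }
  res2 <- list(mk2(3, 4, "A"), mk2(7, 6, "B"), mk2(10, 12, "C"))
  s2 <- cohortSummary(res2)
  m <- cbind(sapply(res2, function(r) r$whole$extent1),
             sapply(res2, function(r) r$whole$extent2))
  want <- oracleICC31(m)
  got <- s2$icc[s2$icc$scope == "whole" & s2$icc$metric == "extent", ]
  expect_equal(got$icc, want$icc, tolerance = 1e-12)
  expect_equal(got$ciLow, want$ciLow, tolerance = 1e-12)

  expect_error(cohortSummary(list()), "at least 2")
  expect_error(cohortSummary(res2[1]), "at least 2")
})

test_that("per-view ICC uses only patients with the view included", {
  os <- fullOutlines(c(15, 15))
  mats <- function(side, withBack) {
    m <- matrix(0L, 15, 15); m[seq_len(side), seq_len(side)] <- 5L
    l <- list(front = m)
    if (withBack) l$back <- m
    l
  }
  res <- lapply(1:4, function(i) {
    withBack <- i <= 2  # only 2 patients ever use the back view
    analyzePair(
      drawingFromMats(mats(i + 2, withBack), os, paste0("P", i), "test"),
      drawingFromMats(mats(i + 2, withBack), os, paste0("P", i), "retest"))
  })
  s <- cohortSummary(res)
  backRow <- s$icc[s$icc$scope == "back" & s$icc$metric == "extent", ]
  expect_identical(backRow$n, 2L)
  leftRow <- s$icc[s$icc$scope == "left" & s$icc$metric == "extent", ]
  expect_identical(leftRow$n, 0L)
  expect_true(is.na(leftRow$icc))
})
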