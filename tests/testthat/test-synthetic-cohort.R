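test_that("procedural outlines are deterministic, connected and plausible", {
  for (v in bodyViews()) {
    m1 <- generateOutline(v, c(200, 320))
    m2 <- generateOutline(v, c(200, 320))
    expect_identical(m1, m2)
    expect_identical(oracleClusterCount(m1, 4), 1L)  # single silhouette
    frac <- mean(m1)
    expect_gte(frac, 0.2)
    expect_lte(frac, 0.6)
  }
  expect_error(generateOutline("front", c(32, 32)), "64")
  # dims must be respected at other aspect ratios too
  m <- generateOutline("left", c(96, 64))
  expect_identical(dim(m), c(96L, 64L))
  expect_true(mean(m) >= 0.2 && mean(m) <= 0.6)
})

test_that("zero perturbation reproduces the test drawing exactly", {
  p <- smallSimParams(perturb = perturbParams(0, 0, 0, 0))
  pair <- generatePair(p, "P1", seed = 21)
  for (v in bodyViews())
    expect_identical(intensities(mergedView(pair$test, v)),
                     intensities(mergedView(pair$retest, v)))
  res <- analyzePair(pair$test, pair$retest)
  inc <- res$views[res$views$included, ]
  expect_true(all(inc$jaccard == 1))
})

test_that("full dropout without additions empties the retest", {
  p <- smallSimParams(perturb = perturbParams(0, 0, dropoutP = 1,
                                              additionP = 0))
  pair <- generatePair(p, "P1", seed = 4)
  expect_gt(sum(sapply(bodyViews(), function(v)
    symptomExtent(mergedView(pair$test, v)))), 0)
  for (v in bodyViews())
    expect_identical(symptomExtent(mergedView(pair$retest, v)), 0L)
})

test_that("pairs and cohorts are reproducible, and prefix-stable in n", {
  p <- smallSimParams(nPatients = 3)
  a <- generatePair(p, "P1", seed = 9)
  b <- generatePair(p, "P1", seed = 9)
  for (v in bodyViews())
    expect_identical(intensities(mergedView(a$test, v)),
                     intensities(mergedView(b$test, v)))
  expect_identical(a$truth, b$truth)

  c1 <- generateCohort(p)
  c2 <- generateCohort(p)
  expect_identical(lapply(c1, `[[`, "truth"), lapply(c2, `[[`, "truth"))
  # adding patients never perturbs earlier ones
  c3 <- generateCohort(smallSimParams(nPatients = 5))
  expect_identical(c1[[2]]$truth, c3[[2]]$truth)
  expect_identical(intensities(mergedView(c1[[2]]$test, "front")),
                   intensities(mergedView(c3[[2]]$test, "front")))

  expect_error(simParams(nPatients = 0), "nPatients")
})

test_that("generated drawings pass validation", {
  p <- smallSimParams(nPatients = 4, seed = 2)
  for (pair in generateCohort(p)) {
    expect_identical(nrow(validateDrawing(pair$test)), 0L)
    expect_identical(nrow(validateDrawing(pair$retest)), 0L)
  }
})

test_that("drawn-cluster counts track the configured distribution", {
  p <- smallSimParams(nPatients = 150, dims = c(64, 64),
                      clustersMean = c(front = 5.5, back = 4.9,
                                       left = 4.5, right = 4.2),
                      clustersSD = c(front = 7.3, back = 5.7,
                                     left = 5.2, right = 5.4),
                      blobRadiusMeanlog = log(4), seed = 31)
  coh <- generateCohort(p)
  for (v in bodyViews()) {
    counts <- sapply(coh, function(pair)
      pair$truth$drawnClusters[pair$truth$view == v &
                                 pair$truth$session == "test"])
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - p@clustersMean[[v]]), 3 * se + 1e-9)
    # drawn-cluster count bounds the connected-component count
    first <- coh[[1]]
    expect_lte(clusterCount(mergedView(first$test, v)),
               max(first$truth$drawnClusters[first$truth$view == v &
                                               first$truth$session == "test"],
                   0L) * 3L)  # each cluster has at most 3 disks
  }
})

test_that("expected Jaccard decreases with translation and dropout", {
  meanJaccard <- function(perturb, n = 100, seed = 61) {
    p <- simParams(nPatients = n, dims = c(128, 80),
                   clustersMean = 3, clustersSD = 3,
                   blobRadiusMeanlog = log(6), blobRadiusSdlog = 0.25,
                   perturb = perturb, seed = seed)
    coh <- generateCohort(p)
    js <- sapply(coh, function(pair)
      analyzePair(pair$test, pair$retest)$whole$jaccard)
    mean(js, na.rm = TRUE)
  }
  jTrans <- sapply(c(0, 4, 12), function(s)
    meanJaccard(perturbParams(s, 0, 0, 0)))
  expect_true(all(diff(jTrans) < 0))
  expect_equal(jTrans[1], 1)

  jDrop <- sapply(c(0, 0.4, 0.8), function(q)
    meanJaccard(perturbParams(0, 0, q, 0)))
  expect_true(all(diff(jDrop) < 0))
})

test_that("extent ICC recovery from a shared/noise variance construction", {
  # per-patient true extent with between-subject variance 0.9, retest noise
  # variance 0.1: ICC(3,1) should concentrate near 0.9 at n = 200
  set.seed(19)
  iccs <- replicate(120, {
    b <- rnorm(200, 0, sqrt(0.9))
    m <- cbind(b + rnorm(200, 0, sqrt(0.1)), b + rnorm(200, 0, sqrt(0.1)))
    icc31(m)$icc
  })
  expect_lt(abs(mean(iccs) - 0.9), 0.02)
})
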