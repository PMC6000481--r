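# Evaluate expr under a local RNG stream, restoring the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-patient substream seeds split from the master seed, so
# extending a cohort never changes the draws of earlier patients.
.patientSeed <- function(masterSeed, index) {
  as.integer((as.numeric(masterSeed) %% 2147483647 * 48271 +
                index * 1000003) %% 2147483646 + 1)
}

#' Construct retest perturbation parameters
#'
#' @param translationSigma SD in pixels of the Gaussian jitter applied to
#'   each cluster centre at retest.
#' @param boundarySigma SD in pixels of the signed radius change (boundary
#'   grow/shrink) per cluster.
#' @param dropoutP Probability a cluster is omitted at retest (a forgotten
#'   region).
#' @param additionP Probability a new cluster appears per view at retest.
#' @return A [PerturbParams-class].
#' @export
perturbParams <- function(translationSigma = 5, boundarySigma = 1,
                          dropoutP = 0.05, additionP = 0.05) {
  new("PerturbParams", translationSigma = translationSigma,
      boundarySigma = boundarySigma, dropoutP = dropoutP,
      additionP = additionP)
}

#' Construct synthetic-cohort parameters
#'
#' Defaults encode the simulated study conditions: 25 test-retest pairs on a
#' 320 x 200 px canvas per view (the 1.6 aspect ratio of the acquisition
#' tablet, scaled down for simulation); drawn-cluster counts per view follow
#' a negative binomial with the per-view means and SDs observed in chronic
#' pain outpatients (front 5.5 (7.3), back 4.9 (5.7), left 4.5 (5.2), right
#' 4.2 (5.4)); blobs are log-normal disks with median radius 10 px; VAS
#' levels are uniform on 1..10; and the retest perturbation uses a centre
#' jitter of about half a blob radius, which for two equal disks corresponds
#' to a per-cluster overlap (Jaccard) near 0.45.
#'
#' @param nPatients Number of simulated patients.
#' @param dims Raster `c(rows, cols)` per view.
#' @param clustersMean,clustersSD Per-view negative-binomial mean and SD of
#'   the drawn-cluster count (named by view, or scalars recycled).
#' @param blobRadiusMeanlog,blobRadiusSdlog Log-normal parameters of the
#'   primary disk radius in pixels.
#' @param vasProbs Weights for VAS levels 1..10.
#' @param perturb A [PerturbParams-class].
#' @param seed Master seed.
#' @return A [SimParams-class].
#' @export
simParams <- function(nPatients = 25,
                      dims = c(320, 200),
                      clustersMean = c(front = 5.5, back = 4.9,
                                       left = 4.5, right = 4.2),
                      clustersSD = c(front = 7.3, back = 5.7,
                                     left = 5.2, right = 5.4),
                      blobRadiusMeanlog = log(10),
                      blobRadiusSdlog = 0.3,
                      vasProbs = rep(1, 10),
                      perturb = perturbParams(),
                      seed = 1) {
  expand <- function(x) {
    if (is.null(names(x)) && length(x) == 1L)
      x <- stats::setNames(rep(x, 4L), bodyViews())
    x[bodyViews()]
  }
  new("SimParams", nPatients = as.integer(nPatients),
      dims = as.integer(dims),
      clustersMean = expand(clustersMean), clustersSD = expand(clustersSD),
      blobRadiusMeanlog = blobRadiusMeanlog,
      blobRadiusSdlog = blobRadiusSdlog,
      vasProbs = vasProbs, perturb = perturb, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: %d patient(s), %d x %d px/view, seed %d\n",
              object@nPatients, object@dims[1L], object@dims[2L],
              object@seed))
  cat(sprintf("  clusters/view (NB mean): %s\n",
              paste(sprintf("%s %.1f", names(object@clustersMean),
                            object@clustersMean), collapse = ", ")))
  p <- object@perturb
  cat(sprintf(
    "  perturbation: shift sd %.1f px, boundary sd %.1f px, dropout %.2f, addition %.2f\n",
    p@translationSigma, p@boundarySigma, p@dropoutP, p@additionP))
})

#' Generate a procedural body-outline mask
#'
#' A deterministic schematic silhouette (head, neck, torso, arms, legs;
#' side views are narrower single-leg profiles) rasterized onto the given
#' canvas. The silhouette is a single connected component occupying roughly
#' 20-60% of the canvas, which is all the downstream metrics require of an
#' outline. Identical inputs always yield identical masks.
#'
#' @param view One of [bodyViews()].
#' @param dims `c(rows, cols)`, at least 64 x 64.
#' @return Logical matrix; `TRUE` = body interior.
#' @export
generateOutline <- function(view, dims) {
  view <- match.arg(view, bodyViews())
  if (length(dims) != 2L || any(dims < 64))
    stop("outline canvas must be at least 64 x 64 pixels")
  nr <- as.integer(dims[1L]); nc <- as.integer(dims[2L])
  ys <- (seq_len(nr) - 0.5) / nr
  xs <- (seq_len(nc) - 0.5) / nc
  Y <- matrix(ys, nr, nc)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  rect <- function(x0, x1, y0, y1) X >= x0 & X <= x1 & Y >= y0 & Y <= y1
  ell <- function(cx, cy, rx, ry) ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
  if (view %in% c("front", "back")) {
    torso <- if (view == "front") rect(0.30, 0.70, 0.16, 0.52)
             else rect(0.29, 0.71, 0.16, 0.52)
    mask <- ell(0.5, 0.09, 0.085, 0.06) |
      rect(0.46, 0.54, 0.08, 0.20) |
      torso |
      rect(0.17, 0.32, 0.18, 0.56) | rect(0.68, 0.83, 0.18, 0.56) |
      rect(0.32, 0.48, 0.50, 0.95) | rect(0.52, 0.68, 0.50, 0.95)
  } else {
    foot <- if (view == "right") rect(0.36, 0.72, 0.90, 0.96)
            else rect(0.28, 0.64, 0.90, 0.96)
    mask <- ell(0.5, 0.09, 0.10, 0.06) |
      rect(0.46, 0.54, 0.08, 0.20) |
      rect(0.33, 0.67, 0.16, 0.54) |
      rect(0.36, 0.64, 0.52, 0.95) |
      foot
  }
  mask
}

#' Standard outline set
#'
#' The four procedural views of [generateOutline()] bundled as an
#' [OutlineSet-class].
#'
#' @param dims `c(rows, cols)` per view.
#' @return An [OutlineSet-class].
#' @export
standardOutlines <- function(dims = c(320, 200)) {
  masks <- lapply(bodyViews(), generateOutline, dims = dims)
  names(masks) <- bodyViews()
  outlineSet(masks)
}

# Paint filled disks (rows of [cy, cx, r] in pixel coordinates) onto an
# integer matrix at the given VAS value.
.fillDisks <- function(mat, disks, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  for (i in seq_len(nrow(disks))) {
    cy <- disks[i, 1L]; cx <- disks[i, 2L]; r <- disks[i, 3L]
    r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
    c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
    if (r0 > r1 || c0 > c1) next
    dy <- (r0:r1) - cy
    dx <- (c0:c1) - cx
    inside <- outer(dy^2, dx^2, "+") <= r^2
    block <- mat[r0:r1, c0:c1, drop = FALSE]
    block[inside] <- pmax(block[inside], value)
    mat[r0:r1, c0:c1] <- block
  }
  mat
}

# Sample one ground-truth cluster: centre at a uniform interior pixel of
# the view's outline, 1-3 disks, log-normal primary radius.
.sampleCluster <- function(params, view, outline, symptom, vas) {
  mask <- outline@masks[[view]]
  interior <- which(mask)
  centre <- interior[sample.int(length(interior), 1L)]
  nr <- nrow(mask)
  cy <- ((centre - 1L) %% nr) + 1L
  cx <- ((centre - 1L) %/% nr) + 1L
  r <- stats::rlnorm(1L, params@blobRadiusMeanlog, params@blobRadiusSdlog)
  r <- max(2, min(r, min(dim(mask)) / 4))
  nDisks <- sample.int(3L, 1L)
  disks <- matrix(c(cy, cx, r), 1L, 3L)
  if (nDisks > 1L) {
    ang <- stats::runif(nDisks - 1L, 0, 2 * pi)
    d <- stats::runif(nDisks - 1L, 0, r)
    disks <- rbind(disks,
                   cbind(cy + d * sin(ang), cx + d * cos(ang),
                         rep(0.6 * r, nDisks - 1L)))
  }
  list(view = view, symptom = symptom, vas = vas, disks = disks)
}

# Rasterize ground-truth clusters into a BodyDrawing (one SymptomMap per
# symptom and view, clipped to the outline interior).
.rasterizeDrawing <- function(clusters, specs, outline, patientId, session) {
  dims <- outline@dims
  symMaps <- lapply(seq_along(specs), function(si) {
    maps <- lapply(bodyViews(), function(v) {
      m <- matrix(0L, dims[1L], dims[2L])
      for (cl in clusters)
        if (cl$symptom == si && cl$view == v)
          m <- .fillDisks(m, cl$disks, cl$vas)
      m[!outline@masks[[v]]] <- 0L
      symptomMap(v, m)
    })
    names(maps) <- bodyViews()
    list(spec = specs[[si]], maps = maps)
  })
  bodyDrawing(patientId, session, outline, symMaps)
}

.randomSpec <- function(params) {
  nd <- sample.int(3L, 1L)
  vas <- sample.int(10L, 1L, prob = params@vasProbs)
  symptomSpec(
    descriptors = sample(symptomDescriptors(), nd),
    depths = sample(depthCategories(), sample.int(2L, 1L)),
    vasMax = vas, vasMin = sample.int(vas + 1L, 1L) - 1L,
    currentlyPresent = stats::runif(1L) < 0.7,
    worstInterval = sample(dayIntervals(), 1L),
    burden = sample.int(11L, 1L) - 1L)
}

#' Generate one synthetic test-retest drawing pair
#'
#' The test drawing is sampled from the cohort parameters: a small number of
#' symptoms, per-view drawn-cluster counts from the negative binomial, each
#' cluster a union of 1-3 filled disks at a single VAS level, placed at a
#' uniformly sampled interior pixel of the view's outline (clusters may
#' merge by overlap, so the drawn-cluster count can exceed the connected
#' component count, as in real drawings). The retest drawing reuses the test
#' clusters, applying the perturbation model: per-cluster dropout, centre
#' translation, boundary grow/shrink, and per-view cluster addition. With a
#' zero perturbation the retest is pixel-identical to the test.
#'
#' @param params A [SimParams-class].
#' @param patientId Patient identifier.
#' @param seed Substream seed for this pair; the same seed always reproduces
#'   the same pair.
#' @return List with `test` and `retest` ([BodyDrawing-class]) plus
#'   `truth`, a data.frame of the ground-truth drawn-cluster counts per
#'   view and session.
#' @export
generatePair <- function(params, patientId, seed = params@seed) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  .withSeed(seed, {
    outline <- standardOutlines(params@dims)
    p <- params@perturb
    nSym <- 1L + stats::rpois(1L, 1)
    specs <- lapply(seq_len(nSym), function(i) .randomSpec(params))
    clusters <- list()
    for (v in bodyViews()) {
      mu <- params@clustersMean[[v]]
      size <- mu^2 / (params@clustersSD[[v]]^2 - mu)
      nClust <- stats::rnbinom(1L, size = size, mu = mu)
      for (j in seq_len(nClust)) {
        si <- sample.int(nSym, 1L)
        clusters[[length(clusters) + 1L]] <-
          .sampleCluster(params, v, outline, si, specs[[si]]@vasMax)
      }
    }
    test <- .rasterizeDrawing(clusters, specs, outline, patientId, "test")

    retest <- list()
    for (cl in clusters) {
      if (stats::runif(1L) < p@dropoutP) next
      shift <- stats::rnorm(2L, 0, p@translationSigma)
      dr <- stats::rnorm(1L, 0, p@boundarySigma)
      cl$disks[, 1L] <- cl$disks[, 1L] + shift[1L]
      cl$disks[, 2L] <- cl$disks[, 2L] + shift[2L]
      cl$disks[, 3L] <- pmax(1, cl$disks[, 3L] + dr)
      retest[[length(retest) + 1L]] <- cl
    }
    for (v in bodyViews()) {
      if (stats::runif(1L) < p@additionP) {
        si <- sample.int(nSym, 1L)
        retest[[length(retest) + 1L]] <-
          .sampleCluster(params, v, outline, si, specs[[si]]@vasMax)
      }
    }
    retestDrawing <- .rasterizeDrawing(retest, specs, outline, patientId,
                                       "retest")
    countBy <- function(cls) vapply(bodyViews(), function(v)
      sum(vapply(cls, function(cl) cl$view == v, logical(1))), integer(1))
    truth <- data.frame(view = rep(bodyViews(), 2L),
                        session = rep(c("test", "retest"),
                                      each = length(bodyViews())),
                        drawnClusters = c(countBy(clusters), countBy(retest)),
                        stringsAsFactors = FALSE)
    list(test = test, retest = retestDrawing, truth = truth)
  })
}

#' Generate a synthetic test-retest cohort
#'
#' `nPatients` independent pairs; each patient's RNG substream is split
#' deterministically from the master seed by patient index, so cohorts are
#' reproducible and adding patients never perturbs earlier ones.
#'
#' @param params A [SimParams-class].
#' @return List of [generatePair()] results, one per patient, named by
#'   patient id (`P001`, `P002`, ...).
#' @export
generateCohort <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  ids <- sprintf("P%03d", seq_len(params@nPatients))
  pairs <- lapply(seq_len(params@nPatients), function(i)
    generatePair(params, ids[i], seed = .patientSeed(params@seed, i)))
  names(pairs) <- ids
  pairs
}
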