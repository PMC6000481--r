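#' Label connected clusters of a presence mask
#'
#' Connected-component labelling of a binarized drawing. Neighbourhood is
#' either 4-connectivity (edge-sharing pixels) or 8-connectivity (edges and
#' diagonals). The default 8 is the 2-D analogue of the 26-neighbourhood
#' used by common neuroimaging cluster tools; two pixels touching only at a
#' corner are one cluster under 8 and two under 4.
#'
#' Internally the foreground pixels form the vertices of an adjacency graph
#' (edges from the vectorized neighbour shifts) whose components are the
#' clusters.
#'
#' @param mask Logical matrix (or a map accepted by [binarize()]).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of the same shape; 0 = background, clusters are
#'   numbered 1..k.
#' @export
labelClusters <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) || !is.logical(mask))
    mask <- binarize(mask)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(labels)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    r1 <- seq.int(max(1L, 1L - dr), min(nr, nr - dr))
    c1 <- seq.int(max(1L, 1L - dc), min(nc, nc - dc))
    both <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    w <- which(both)
    if (length(w)) {
      rr <- ((w - 1L) %% length(r1)) + 1L
      cc <- ((w - 1L) %/% length(r1)) + 1L
      from <- c(from, (c1[cc] - 1L) * nr + r1[rr])
      to <- c(to, (c1[cc] + dc - 1L) * nr + r1[rr] + dr)
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(match(from, fg), match(to, fg)))
  labels[fg] <- as.integer(igraph::components(g)$membership)
  labels
}

#' Number of symptom clusters
#'
#' A cluster is a connected component of the binarized drawing (see
#' [labelClusters()] for the connectivity definitions).
#'
#' @inheritParams labelClusters
#' @param map A map or logical mask.
#' @return Non-negative integer count.
#' @export
clusterCount <- function(map, connectivity = 8)
  as.integer(max(labelClusters(map, connectivity), 0L))

#' Symptom extent in pixels
#'
#' The number of drawn (nonzero) pixels inside the body outline.
#'
#' @param map A [SymptomMap-class], [MergedMap-class] or integer matrix.
#' @param outline Optional [OutlineSet-class] or logical mask; when given,
#'   the map is restricted to the outline interior first.
#' @return Pixel count.
#' @export
symptomExtent <- function(map, outline = NULL) {
  m <- if (is.matrix(map)) map else intensities(map)
  if (!is.null(outline)) {
    mask <- if (is(outline, "OutlineSet")) outlineMask(outline, mapView(map))
            else outline
    if (!identical(dim(mask), dim(m)))
      stop("outline and map dimensions differ")
    m[!mask] <- 0L
  }
  sum(m > 0L)
}

#' Overlap statistics of two drawings on one view
#'
#' Intersection, union and Jaccard index of the binarized (threshold 0),
#' outline-restricted presence masks. The Jaccard index is undefined (NA)
#' when the union is empty; it is never coerced to 0 or 1.
#'
#' @param mapA,mapB Maps or matrices of identical geometry.
#' @param outline Optional outline restriction as in [symptomExtent()].
#' @return List with `intersection`, `union` (pixel counts) and `jaccard`.
#' @export
overlapStats <- function(mapA, mapB, outline = NULL) {
  a <- if (is.matrix(mapA)) mapA > 0L else binarize(mapA)
  b <- if (is.matrix(mapB)) mapB > 0L else binarize(mapB)
  if (!identical(dim(a), dim(b)))
    stop("maps have different dimensions")
  if (!is.null(outline)) {
    mask <- if (is(outline, "OutlineSet")) {
      v <- if (is.matrix(mapA)) NULL else mapView(mapA)
      if (is.null(v)) stop("outline restriction of bare matrices needs a mask")
      outlineMask(outline, v)
    } else outline
    if (!identical(dim(mask), dim(a)))
      stop("outline and map dimensions differ")
    a <- a & mask; b <- b & mask
  }
  i <- sum(a & b); u <- sum(a | b)
  list(intersection = i, union = u,
       jaccard = if (u > 0L) i / u else NA_real_)
}

#' Merge and restrict one view of a drawing
#'
#' Convenience: pixelwise-maximum merge of all the drawing's symptom maps
#' on a view, restricted to the body outline.
#'
#' @param drawing A [BodyDrawing-class].
#' @param view One of [bodyViews()].
#' @return A [MergedMap-class].
#' @export
mergedView <- function(drawing, view) {
  stopifnot(is(drawing, "BodyDrawing"))
  view <- match.arg(view, bodyViews())
  maps <- lapply(drawing@symptoms, function(s) s$maps[[view]])
  mm <- mergeSymptomMaps(maps, view = view, dims = drawing@outlines@dims)
  restrictToOutline(mm, drawing@outlines)
}

#' Test-retest metrics for one drawing pair
#'
#' Merges the symptoms of each drawing per view (maximum VAS per pixel),
#' then computes per-view extent, cluster count, intersection, union and
#' Jaccard index, plus whole-drawing totals and view aggregates.
#'
#' View exclusion: with `excludeWhen = "both"` (default) a view is excluded
#' only when it is blank in *both* sessions; a view drawn in exactly one
#' session stays in and contributes Jaccard 0, penalising forgotten views.
#' The alternative reading, excluding a view blank in *either* session, is
#' available as `excludeWhen = "either"`.
#'
#' Whole-drawing extent/cluster totals are sums over included views; the
#' whole-drawing Jaccard pools pixels across included views into a single
#' ratio (an undefined ratio propagates as NA).
#'
#' @param test,retest [BodyDrawing-class] objects of the same patient on
#'   the same outline set.
#' @param connectivity Cluster connectivity, 4 or 8 (default 8).
#' @param excludeWhen `"both"` (default) or `"either"`; see Details.
#' @return A `reproPair` object: list with `patientId`, `views` (one row per
#'   view: `extent1`, `extent2`, `clusters1`, `clusters2`, `intersection`,
#'   `union`, `jaccard`, `included`), `whole` (one-row data.frame of pooled
#'   values) and `aggregates` (max and mean of per-view Jaccard over
#'   included views).
#' @export
analyzePair <- function(test, retest, connectivity = 8,
                        excludeWhen = c("both", "either")) {
  stopifnot(is(test, "BodyDrawing"), is(retest, "BodyDrawing"))
  excludeWhen <- match.arg(excludeWhen)
  if (!identical(test@patientId, retest@patientId))
    stop("drawings belong to different patients")
  if (!identical(test@outlines@dims, retest@outlines@dims) ||
      !identical(test@outlines@masks, retest@outlines@masks))
    stop("drawings use different outline sets")
  rows <- lapply(bodyViews(), function(v) {
    m1 <- mergedView(test, v)
    m2 <- mergedView(retest, v)
    e1 <- symptomExtent(m1); e2 <- symptomExtent(m2)
    ov <- overlapStats(m1, m2)
    data.frame(view = v, extent1 = e1, extent2 = e2,
               clusters1 = clusterCount(m1, connectivity),
               clusters2 = clusterCount(m2, connectivity),
               intersection = ov$intersection, union = ov$union,
               jaccard = ov$jaccard,
               included = if (excludeWhen == "both") e1 > 0L || e2 > 0L
                          else e1 > 0L && e2 > 0L,
               stringsAsFactors = FALSE)
  })
  views <- do.call(rbind, rows)
  inc <- views[views$included, , drop = FALSE]
  wholeUnion <- sum(inc$union)
  whole <- data.frame(
    extent1 = sum(inc$extent1), extent2 = sum(inc$extent2),
    clusters1 = sum(inc$clusters1), clusters2 = sum(inc$clusters2),
    intersection = sum(inc$intersection), union = wholeUnion,
    jaccard = if (wholeUnion > 0L) sum(inc$intersection) / wholeUnion
              else NA_real_)
  aggregates <- list(
    jaccardMax = if (nrow(inc)) max(inc$jaccard) else NA_real_,
    jaccardMean = if (nrow(inc)) mean(inc$jaccard) else NA_real_)
  structure(list(patientId = test@patientId, views = views,
                 whole = whole, aggregates = aggregates,
                 connectivity = connectivity, excludeWhen = excludeWhen),
            class = "reproPair")
}

#' @export
print.reproPair <- function(x, ...) {
  cat(sprintf("Test-retest pair, patient %s (connectivity %d)\n",
              x$patientId, x$connectivity))
  print(x$views, row.names = FALSE)
  cat(sprintf("whole drawing: extent %d/%d, clusters %d/%d, Jaccard %s\n",
              x$whole$extent1, x$whole$extent2, x$whole$clusters1,
              x$whole$clusters2, formatC(x$whole$jaccard, digits = 3)))
  invisible(x)
}

.iccRowSafe <- function(x1, x2, scope, metric, alpha) {
  n <- length(x1)
  res <- tryCatch(icc31(cbind(x1, x2), alpha = alpha),
                  error = function(e) NULL)
  data.frame(scope = scope, metric = metric, n = n,
             icc = if (is.null(res)) NA_real_ else res$icc,
             ciLow = if (is.null(res)) NA_real_ else res$ciLow,
             ciHigh = if (is.null(res)) NA_real_ else res$ciHigh,
             stringsAsFactors = FALSE)
}

#' Cohort-level test-retest summary
#'
#' Aggregates per-pair results into the reliability table of a test-retest
#' study: mean and SD of the per-patient (whole-drawing, pooled) Jaccard
#' index, and ICC(3,1) with 95% CI of symptom extent and of cluster count,
#' for the whole drawing and for each single view. Per-view ICCs use only
#' the patients whose view is included; a view with fewer than 2 such
#' patients (or a degenerate ratings matrix) is reported as NA.
#'
#' @param results List of `reproPair` objects from [analyzePair()].
#' @param alpha Two-sided level for the ICC confidence intervals.
#' @return List with `patients` (one row per pair), `jaccardMean`,
#'   `jaccardSD`, `nJaccard`, and `icc` (long data.frame: scope x metric).
#' @export
cohortSummary <- function(results, alpha = 0.05) {
  if (length(results) < 2L)
    stop("cohort summary needs at least 2 test-retest pairs")
  stopifnot(all(vapply(results, inherits, logical(1), "reproPair")))
  patients <- do.call(rbind, lapply(results, function(r)
    cbind(data.frame(patientId = r$patientId, stringsAsFactors = FALSE),
          r$whole,
          jaccardMeanViews = r$aggregates$jaccardMean,
          jaccardMaxViews = r$aggregates$jaccardMax)))
  j <- patients$jaccard[!is.na(patients$jaccard)]
  icc <- rbind(
    .iccRowSafe(patients$extent1, patients$extent2, "whole", "extent", alpha),
    .iccRowSafe(patients$clusters1, patients$clusters2, "whole", "clusters",
                alpha))
  for (v in bodyViews()) {
    sub <- do.call(rbind, lapply(results, function(r) {
      row <- r$views[r$views$view == v, , drop = FALSE]
      if (row$included) row else NULL
    }))
    for (metric in c("extent", "clusters")) {
      c1 <- paste0(if (metric == "extent") "extent" else "clusters", "1")
      c2 <- paste0(if (metric == "extent") "extent" else "clusters", "2")
      icc <- rbind(icc, if (is.null(sub) || nrow(sub) < 2L)
        data.frame(scope = v, metric = metric,
                   n = if (is.null(sub)) 0L else nrow(sub),
                   icc = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                   stringsAsFactors = FALSE)
        else .iccRowSafe(sub[[c1]], sub[[c2]], v, metric, alpha))
    }
  }
  list(patients = patients,
       jaccardMean = if (length(j)) mean(j) else NA_real_,
       jaccardSD = if (length(j) > 1L) stats::sd(j) else NA_real_,
       nJaccard = length(j),
       icc = icc)
}

#' Write a cohort summary as CSV
#'
#' Two files: `<prefix>_patients.csv` (one row per test-retest pair) and
#' `<prefix>_summary.csv` (Jaccard mean/SD and the ICC block, mirroring the
#' row structure of a test-retest reliability table).
#'
#' @param summary Result of [cohortSummary()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
writeCohortSummary <- function(summary, prefix) {
  pf <- paste0(prefix, "_patients.csv")
  sf <- paste0(prefix, "_summary.csv")
  utils::write.csv(summary$patients, pf, row.names = FALSE)
  head <- data.frame(scope = "whole", metric = "jaccard",
                     n = summary$nJaccard, icc = NA_real_,
                     ciLow = NA_real_, ciHigh = NA_real_,
                     mean = summary$jaccardMean, sd = summary$jaccardSD,
                     stringsAsFactors = FALSE)
  tab <- summary$icc
  tab$mean <- NA_real_; tab$sd <- NA_real_
  utils::write.csv(rbind(head, tab), sf, row.names = FALSE)
  invisible(c(patients = pf, summary = sf))
}
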