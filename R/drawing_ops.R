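#' Merge symptom maps of one view by pixelwise maximum VAS
#'
#' When a patient draws several symptoms, the maps of each view are merged
#' for reproducibility analysis; the merged intensity at a pixel is the
#' maximum VAS value over all contributing symptoms there. The operation is
#' commutative, associative and idempotent; an empty input yields an
#' all-zero map.
#'
#' @param maps List of [SymptomMap-class] objects, all of the same view and
#'   geometry. May be empty.
#' @param view The view being merged; required when `maps` is empty,
#'   otherwise inferred and cross-checked.
#' @param dims Raster dims, required only when `maps` is empty.
#' @return A [MergedMap-class].
#' @export
#' @examples
#' a <- symptomMap("front", matrix(c(3L, 0L, 0L, 0L), 2))
#' b <- symptomMap("front", matrix(c(7L, 0L, 0L, 2L), 2))
#' intensities(mergeSymptomMaps(list(a, b)))
mergeSymptomMaps <- function(maps, view = NULL, dims = NULL) {
  if (!length(maps)) {
    if (is.null(view) || is.null(dims))
      stop("view and dims are required to merge an empty map list")
    return(new("MergedMap", view = view,
               intensities = matrix(0L, dims[1L], dims[2L]),
               nSymptoms = 0L))
  }
  stopifnot(all(vapply(maps, is, logical(1), "SymptomMap")))
  views <- vapply(maps, function(m) m@view, character(1))
  if (length(unique(views)) != 1L)
    stop("cannot merge maps from different views")
  if (!is.null(view) && view != views[1L])
    stop("maps belong to view '", views[1L], "', not '", view, "'")
  d <- dim(maps[[1L]]@intensities)
  acc <- maps[[1L]]@intensities
  for (m in maps[-1L]) {
    if (!identical(dim(m@intensities), d))
      stop("cannot merge maps of different dimensions")
    acc <- pmax(acc, m@intensities)
  }
  new("MergedMap", view = views[1L], intensities = acc,
      nSymptoms = length(maps))
}

#' Binarize a map to a presence mask
#'
#' Overlap and cluster metrics operate on presence/absence. A pixel is
#' present when its intensity strictly exceeds `threshold`; the default 0
#' means any ink counts, matching a pixel-count reading of drawn extent. At
#' threshold 10 the mask is empty for any valid map (VAS never exceeds 10).
#'
#' @param map A [SymptomMap-class], [MergedMap-class], or integer matrix.
#' @param threshold VAS cutoff in `[0, 10]`.
#' @return Logical matrix.
#' @export
binarize <- function(map, threshold = 0) {
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 10)
    stop("threshold must be a single value in [0, 10]")
  m <- if (is.matrix(map)) map else intensities(map)
  m > threshold
}

#' Restrict a map to the body-outline interior
#'
#' Sets intensities outside the outline to zero and leaves interior pixels
#' unchanged; idempotent.
#'
#' @param map A [SymptomMap-class] or [MergedMap-class].
#' @param outline An [OutlineSet-class], or a logical interior mask for the
#'   map's view.
#' @return Object of the same class as `map`.
#' @export
restrictToOutline <- function(map, outline) {
  mask <- if (is(outline, "OutlineSet")) outlineMask(outline, mapView(map))
          else outline
  m <- intensities(map)
  if (!identical(dim(mask), dim(m)))
    stop("outline and map dimensions differ")
  m[!mask] <- 0L
  out <- map
  out@intensities <- m
  out
}
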