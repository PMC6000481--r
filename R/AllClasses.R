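#' @import methods
NULL

#' The four body views
#'
#' Drawings are acquired on four views of a body outline; every drawing
#' addresses all four, and a view may be blank.
#'
#' @return Character vector `c("front", "back", "left", "right")`.
#' @export
#' @examples
#' bodyViews()
bodyViews <- function() c("front", "back", "left", "right")

.validViews <- function(x) all(x %in% bodyViews())

#' OutlineSet: binary body-outline masks for the four views
#'
#' One outline set holds, for each of the four body views, a logical raster
#' whose `TRUE` pixels form the body interior. All drawing and all metrics
#' are restricted to this interior. The four masks share one raster geometry
#' (rows x cols, row-major, origin top-left).
#'
#' @slot masks Named list (`front`, `back`, `left`, `right`) of logical
#'   matrices of identical dimension.
#' @slot dims Integer vector `c(rows, cols)`.
#' @export
setClass("OutlineSet", representation(masks = "list", dims = "integer"))

setValidity("OutlineSet", function(object) {
  msgs <- character(0)
  if (!identical(sort(names(object@masks)), sort(bodyViews())))
    msgs <- c(msgs, "masks must be named with exactly the four body views")
  if (length(object@dims) != 2L || any(object@dims < 1L))
    msgs <- c(msgs, "dims must be two positive integers (rows, cols)")
  for (v in names(object@masks)) {
    m <- object@masks[[v]]
    if (!is.matrix(m) || !is.logical(m))
      msgs <- c(msgs, sprintf("mask '%s' must be a logical matrix", v))
    else {
      if (!identical(dim(m), as.integer(object@dims)))
        msgs <- c(msgs, sprintf("mask '%s' does not match dims", v))
      if (!any(m))
        msgs <- c(msgs, sprintf("mask '%s' has no interior pixel", v))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SymptomSpec: textual specification of one symptom
#'
#' The descriptive record a patient enters for each symptom before drawing
#' it: sensation descriptors (several allowed), perceived depth categories,
#' maximal and minimal intensity on a 0-10 visual analog scale (VAS),
#' whether the symptom is currently present, the 6-hour day interval in
#' which it is worst, and its perceived burden (VAS 0-10).
#'
#' @slot descriptors Character vector of sensation terms; non-empty. Terms
#'   outside [symptomDescriptors()] are treated as free text.
#' @slot depths Character vector, non-empty subset of [depthCategories()].
#' @slot vasMax,vasMin Integer VAS 0-10 with `vasMin <= vasMax`.
#' @slot currentlyPresent Logical flag.
#' @slot worstInterval One of [dayIntervals()].
#' @slot burden Integer VAS 0-10.
#' @export
setClass("SymptomSpec", representation(
  descriptors = "character", depths = "character",
  vasMax = "integer", vasMin = "integer",
  currentlyPresent = "logical", worstInterval = "character",
  burden = "integer"))

setValidity("SymptomSpec", function(object) {
  msgs <- character(0)
  if (!length(object@descriptors))
    msgs <- c(msgs, "descriptors must be non-empty")
  if (!length(object@depths) || !all(object@depths %in% depthCategories()))
    msgs <- c(msgs, "depths must be a non-empty subset of depthCategories()")
  for (f in c("vasMax", "vasMin", "burden")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0L || v > 10L)
      msgs <- c(msgs, sprintf("%s must be a single integer in 0..10", f))
  }
  if (length(object@vasMin) == 1L && length(object@vasMax) == 1L &&
      !is.na(object@vasMin) && !is.na(object@vasMax) &&
      object@vasMin > object@vasMax)
    msgs <- c(msgs, "vasMin must not exceed vasMax")
  if (length(object@worstInterval) != 1L ||
      !object@worstInterval %in% dayIntervals())
    msgs <- c(msgs, "worstInterval must be one of dayIntervals()")
  if (length(msgs)) msgs else TRUE
})

#' FindingSpec: a doctor's diagnostic finding
#'
#' Doctors record findings from the bodily examination with the same
#' drawing mechanism as patient symptoms, but with a categorised finding
#' vocabulary (see [findingVocabulary()]). Terms not in the category's
#' vocabulary are flagged as free text.
#'
#' @slot category One of the finding categories in [findingVocabulary()].
#' @slot terms Character vector of finding terms, non-empty.
#' @slot freeText Logical vector parallel to `terms`; `TRUE` where the term
#'   is not in the category's standard vocabulary.
#' @slot depths Non-empty subset of [depthCategories()].
#' @slot vas Integer VAS 0-10.
#' @export
setClass("FindingSpec", representation(
  category = "character", terms = "character", freeText = "logical",
  depths = "character", vas = "integer"))

setValidity("FindingSpec", function(object) {
  msgs <- character(0)
  voc <- findingVocabulary()
  if (length(object@category) != 1L || !object@category %in% names(voc))
    msgs <- c(msgs, "category must be one of the finding categories")
  if (!length(object@terms))
    msgs <- c(msgs, "terms must be non-empty")
  if (length(object@freeText) != length(object@terms))
    msgs <- c(msgs, "freeText must parallel terms")
  if (!length(object@depths) || !all(object@depths %in% depthCategories()))
    msgs <- c(msgs, "depths must be a non-empty subset of depthCategories()")
  if (length(object@vas) != 1L || is.na(object@vas) ||
      object@vas < 0L || object@vas > 10L)
    msgs <- c(msgs, "vas must be a single integer in 0..10")
  if (length(msgs)) msgs else TRUE
})

#' SymptomMap: one symptom's raster on one body view
#'
#' An integer raster of VAS intensities 0-10, aligned to the outline grid of
#' the view. Zero means "not drawn here". The class enforces range and
#' integrality; whether the ink stays inside the body outline is checked by
#' [validateDrawing()] against a specific [OutlineSet-class], since a map on
#' its own carries no outline.
#'
#' @slot view One of [bodyViews()].
#' @slot intensities Integer matrix with values in 0..10.
#' @export
setClass("SymptomMap", representation(view = "character",
                                      intensities = "matrix"))

setValidity("SymptomMap", function(object) {
  msgs <- character(0)
  if (length(object@view) != 1L || !object@view %in% bodyViews())
    msgs <- c(msgs, "view must be one of bodyViews()")
  m <- object@intensities
  if (!is.integer(m))
    msgs <- c(msgs, "intensities must be an integer matrix")
  else if (anyNA(m) || any(m < 0L) || any(m > 10L))
    msgs <- c(msgs, "intensities must lie in 0..10 with no NA")
  if (length(msgs)) msgs else TRUE
})

#' MergedMap: pixelwise-maximum merge of several symptom maps
#'
#' When a patient draws multiple symptoms, the maps of one view are merged
#' for reproducibility analysis by taking the maximum VAS value at each
#' pixel. `nSymptoms` records how many maps contributed.
#'
#' @slot view One of [bodyViews()].
#' @slot intensities Integer matrix, values 0..10.
#' @slot nSymptoms Number of contributing symptom maps.
#' @seealso [mergeSymptomMaps()]
#' @export
setClass("MergedMap", representation(view = "character",
                                     intensities = "matrix",
                                     nSymptoms = "integer"))

setValidity("MergedMap", function(object) {
  msgs <- character(0)
  if (length(object@view) != 1L || !object@view %in% bodyViews())
    msgs <- c(msgs, "view must be one of bodyViews()")
  m <- object@intensities
  if (!is.integer(m) || anyNA(m) || any(m < 0L) || any(m > 10L))
    msgs <- c(msgs, "intensities must be an integer matrix in 0..10")
  if (length(object@nSymptoms) != 1L || object@nSymptoms < 0L)
    msgs <- c(msgs, "nSymptoms must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' BodyDrawing: one acquisition session
#'
#' Everything one patient entered in one sitting: the outline set drawn on,
#' the session label (`test` or `retest`), the gender chosen for the
#' outline, and a list of symptoms, each a [SymptomSpec-class] together with
#' one [SymptomMap-class] per body view (blank maps allowed).
#'
#' Structural consistency (views present, matching dims, VAS ranges) is a
#' validity error; semantic rule violations such as ink outside the outline
#' are deliberately *not* class errors — they are reported by
#' [validateDrawing()], so that files from sources other than the app can be
#' loaded and audited.
#'
#' @slot patientId Character scalar.
#' @slot session `"test"` or `"retest"`.
#' @slot outlineGender `"female"`, `"male"` or `"not_specified"`.
#' @slot outlines An [OutlineSet-class].
#' @slot symptoms List; each element a list with components `spec`
#'   ([SymptomSpec-class]) and `maps` (named list of [SymptomMap-class],
#'   one per view).
#' @export
setClass("BodyDrawing", representation(
  patientId = "character", session = "character",
  outlineGender = "character", outlines = "OutlineSet",
  symptoms = "list"))

setValidity("BodyDrawing", function(object) {
  msgs <- character(0)
  if (length(object@patientId) != 1L || is.na(object@patientId) ||
      !nzchar(object@patientId))
    msgs <- c(msgs, "patientId must be a non-empty string")
  if (length(object@session) != 1L ||
      !object@session %in% c("test", "retest"))
    msgs <- c(msgs, "session must be 'test' or 'retest'")
  if (length(object@outlineGender) != 1L ||
      !object@outlineGender %in% c("female", "male", "not_specified"))
    msgs <- c(msgs, "outlineGender must be female/male/not_specified")
  for (i in seq_along(object@symptoms)) {
    s <- object@symptoms[[i]]
    if (!is.list(s) || !all(c("spec", "maps") %in% names(s))) {
      msgs <- c(msgs, sprintf("symptom %d must have $spec and $maps", i))
      next
    }
    if (!is(s$spec, "SymptomSpec"))
      msgs <- c(msgs, sprintf("symptom %d: spec must be a SymptomSpec", i))
    if (!identical(sort(names(s$maps)), sort(bodyViews())))
      msgs <- c(msgs, sprintf("symptom %d: maps must cover all four views", i))
    else for (v in bodyViews()) {
      mp <- s$maps[[v]]
      if (!is(mp, "SymptomMap") || !identical(mp@view, v) ||
          !identical(dim(mp@intensities), as.integer(object@outlines@dims)))
        msgs <- c(msgs,
          sprintf("symptom %d view %s: map missing, mislabelled or wrong dims",
                  i, v))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PerturbParams: the retest perturbation model
#'
#' The synthetic generator derives a retest drawing from a test drawing by
#' perturbing each drawn cluster: a random translation of its centre, a
#' random grow/shrink of its radius (boundary noise), a chance of dropping
#' the cluster entirely (a forgotten symptom region), and a chance that a
#' new cluster appears per view. Setting everything to zero reproduces the
#' test drawing exactly.
#'
#' @slot translationSigma SD (pixels) of the isotropic Gaussian centre jitter.
#' @slot boundarySigma SD (pixels) of the signed radius change.
#' @slot dropoutP Probability a cluster is omitted at retest.
#' @slot additionP Probability a new cluster appears per view at retest.
#' @export
setClass("PerturbParams", representation(
  translationSigma = "numeric", boundarySigma = "numeric",
  dropoutP = "numeric", additionP = "numeric"))

setValidity("PerturbParams", function(object) {
  msgs <- character(0)
  for (f in c("translationSigma", "boundarySigma")) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msgs <- c(msgs, sprintf("%s must be a single finite non-negative number", f))
  }
  for (f in c("dropoutP", "additionP")) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must be a probability in [0,1]", f))
  }
  if (length(msgs)) msgs else TRUE
})

#' SimParams: full parameterization of the synthetic cohort
#'
#' Defines the simulated study conditions: cohort size, raster geometry,
#' the per-view distribution of cluster counts (negative binomial,
#' parameterized by per-view means and SDs), the blob-size distribution
#' (log-normal radius in pixels), the VAS level distribution, the retest
#' perturbation model and the master seed.
#'
#' @slot nPatients Number of simulated patients (>= 1).
#' @slot dims Raster `c(rows, cols)` per view.
#' @slot clustersMean,clustersSD Named per-view means and SDs of the
#'   drawn-cluster count (negative binomial; SD > sqrt(mean)).
#' @slot blobRadiusMeanlog,blobRadiusSdlog Log-normal parameters of the
#'   primary disk radius, pixels.
#' @slot vasProbs Probability weights for VAS levels 1..10.
#' @slot perturb A [PerturbParams-class].
#' @slot seed Master seed; per-patient substreams are split from it by
#'   patient index, so extending a cohort never changes earlier patients.
#' @seealso [simParams()] for the defaults and their rationale.
#' @export
setClass("SimParams", representation(
  nPatients = "integer", dims = "integer",
  clustersMean = "numeric", clustersSD = "numeric",
  blobRadiusMeanlog = "numeric", blobRadiusSdlog = "numeric",
  vasProbs = "numeric", perturb = "PerturbParams", seed = "integer"))

setValidity("SimParams", function(object) {
  msgs <- character(0)
  if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
      object@nPatients < 1L)
    msgs <- c(msgs, "nPatients must be >= 1")
  if (length(object@dims) != 2L || any(object@dims < 64L))
    msgs <- c(msgs, "dims must be at least 64 x 64")
  if (!identical(sort(names(object@clustersMean)), sort(bodyViews())) ||
      !identical(sort(names(object@clustersSD)), sort(bodyViews())))
    msgs <- c(msgs, "clustersMean and clustersSD must be named by view")
  else {
    if (any(!is.finite(object@clustersMean)) || any(object@clustersMean < 0))
      msgs <- c(msgs, "clustersMean must be finite and non-negative")
    if (any(!is.finite(object@clustersSD)) ||
        any(object@clustersSD^2 <= object@clustersMean))
      msgs <- c(msgs,
        "clustersSD must satisfy SD^2 > mean (negative binomial overdispersion)")
  }
  if (!is.finite(object@blobRadiusMeanlog) ||
      !is.finite(object@blobRadiusSdlog) || object@blobRadiusSdlog < 0)
    msgs <- c(msgs, "blob radius log-normal parameters must be finite")
  if (length(object@vasProbs) != 10L || any(object@vasProbs < 0) ||
      sum(object@vasProbs) <= 0)
    msgs <- c(msgs, "vasProbs must be 10 non-negative weights for VAS 1..10")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})
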