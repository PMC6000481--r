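#' Symptom descriptor vocabulary
#'
#' The sensation descriptors offered to patients (several may be chosen per
#' symptom); terms outside this list are treated as free text. Shipped as a
#' plain CSV under `extdata` so deployments can extend it.
#'
#' @return Character vector of descriptor terms.
#' @export
symptomDescriptors <- function() {
  f <- system.file("extdata", "symptom_descriptors.csv", package = "bodymapr")
  utils::read.csv(f, stringsAsFactors = FALSE)$term
}

#' Symptom depth categories
#'
#' @return The five perceived-depth categories a symptom may be assigned to
#'   (more than one allowed).
#' @export
depthCategories <- function()
  c("on_skin", "beneath_skin", "muscle", "organ", "bone")

#' Six-hour day intervals
#'
#' @return The four 6-hour intervals used for "time of day when the symptom
#'   is worst".
#' @export
dayIntervals <- function()
  c("night_0_6", "morning_6_12", "afternoon_12_18", "evening_18_24")

#' Diagnostic finding vocabulary
#'
#' The categorised finding terms offered to doctors, keyed by examination
#' category. Shipped as CSV under `extdata`.
#'
#' @return Named list of character vectors, one per finding category.
#' @export
findingVocabulary <- function() {
  f <- system.file("extdata", "finding_vocabulary.csv", package = "bodymapr")
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  split(d$term, d$category)
}

#' Construct an OutlineSet
#'
#' @param masks Named list with elements `front`, `back`, `left`, `right`,
#'   each a logical matrix of identical dimension (TRUE = body interior).
#' @return An [OutlineSet-class].
#' @export
#' @examples
#' os <- outlineSet(standardOutlines(c(96, 64))@masks)
outlineSet <- function(masks) {
  if (!is.list(masks) || is.null(names(masks)))
    stop("masks must be a named list")
  miss <- setdiff(bodyViews(), names(masks))
  if (length(miss))
    stop("missing view(s): ", paste(miss, collapse = ", "))
  masks <- masks[bodyViews()]
  dims <- dim(masks[[1L]])
  for (v in bodyViews())
    if (!identical(dim(masks[[v]]), dims))
      stop("outline masks have mismatched dimensions")
  new("OutlineSet", masks = masks, dims = as.integer(dims))
}

#' @describeIn outlineSet Raster dimensions `c(rows, cols)` of an outline set.
#' @param x An [OutlineSet-class].
#' @export
outlineDims <- function(x) {
  stopifnot(is(x, "OutlineSet"))
  x@dims
}

#' @describeIn outlineSet Logical interior mask of one view.
#' @param view One of [bodyViews()].
#' @export
outlineMask <- function(x, view) {
  stopifnot(is(x, "OutlineSet"))
  view <- match.arg(view, bodyViews())
  x@masks[[view]]
}

#' Construct a SymptomSpec
#'
#' @param descriptors Character vector of sensation terms (non-empty).
#' @param depths Subset of [depthCategories()] (non-empty).
#' @param vasMax,vasMin Maximal/minimal intensity, VAS 0-10. Non-integer
#'   slider values are rounded half-up.
#' @param currentlyPresent Is the symptom present right now?
#' @param worstInterval One of [dayIntervals()].
#' @param burden Perceived burden, VAS 0-10.
#' @return A [SymptomSpec-class].
#' @export
symptomSpec <- function(descriptors, depths = "muscle", vasMax = 5L,
                        vasMin = 0L, currentlyPresent = TRUE,
                        worstInterval = "morning_6_12", burden = 5L) {
  new("SymptomSpec", descriptors = as.character(descriptors),
      depths = as.character(depths), vasMax = vasRound(vasMax),
      vasMin = vasRound(vasMin),
      currentlyPresent = as.logical(currentlyPresent),
      worstInterval = as.character(worstInterval), burden = vasRound(burden))
}

#' Round a slider value to an integer VAS level
#'
#' VAS values are stored as integers 0-10; sub-unit entries from continuous
#' sliders are rounded half-up (2.5 -> 3), unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
#' @examples
#' vasRound(c(2.5, 3.49, 3.5))
vasRound <- function(x) as.integer(floor(as.numeric(x) + 0.5))

#' Construct a FindingSpec
#'
#' @param category Finding category, one of `names(findingVocabulary())`.
#' @param terms Finding terms; unknown terms are flagged as free text.
#' @param depths Subset of [depthCategories()].
#' @param vas Intensity, VAS 0-10.
#' @return A [FindingSpec-class].
#' @export
findingSpec <- function(category, terms, depths = "muscle", vas = 5L) {
  voc <- findingVocabulary()
  category <- match.arg(category, names(voc))
  new("FindingSpec", category = category, terms = as.character(terms),
      freeText = !(terms %in% voc[[category]]),
      depths = as.character(depths), vas = vasRound(vas))
}

#' Construct a SymptomMap
#'
#' @param view One of [bodyViews()].
#' @param intensities Numeric/integer matrix of VAS levels 0-10.
#' @return A [SymptomMap-class].
#' @export
symptomMap <- function(view, intensities) {
  m <- intensities
  storage.mode(m) <- "integer"
  new("SymptomMap", view = view, intensities = m)
}

#' @describeIn symptomMap An all-zero map of the given geometry.
#' @param dims `c(rows, cols)`.
#' @export
blankMap <- function(view, dims)
  symptomMap(view, matrix(0L, dims[1L], dims[2L]))

#' Intensity raster of a map
#'
#' @param x A [SymptomMap-class] or [MergedMap-class].
#' @return Integer matrix of VAS levels.
#' @export
intensities <- function(x) {
  stopifnot(is(x, "SymptomMap") || is(x, "MergedMap"))
  x@intensities
}

#' @describeIn intensities The body view a map belongs to.
#' @export
mapView <- function(x) {
  stopifnot(is(x, "SymptomMap") || is(x, "MergedMap"))
  x@view
}

#' Construct a BodyDrawing
#'
#' @param patientId Patient identifier.
#' @param session `"test"` or `"retest"`.
#' @param outlines An [OutlineSet-class].
#' @param symptoms List of `list(spec = , maps = )` entries; see
#'   [BodyDrawing-class]. Default: no symptoms.
#' @param outlineGender `"female"`, `"male"` or `"not_specified"`.
#' @return A [BodyDrawing-class].
#' @export
bodyDrawing <- function(patientId, session, outlines, symptoms = list(),
                        outlineGender = "not_specified") {
  new("BodyDrawing", patientId = as.character(patientId),
      session = session, outlineGender = outlineGender,
      outlines = outlines, symptoms = symptoms)
}

#' Create a drawing with no symptoms
#'
#' All metrics derived from a blank drawing are zero or empty.
#'
#' @inheritParams bodyDrawing
#' @return A [BodyDrawing-class] with zero symptoms.
#' @export
makeBlankDrawing <- function(outlines, patientId, session = "test",
                             outlineGender = "not_specified") {
  stopifnot(is(outlines, "OutlineSet"))
  bodyDrawing(patientId, session, outlines, list(), outlineGender)
}

#' Add a symptom to a drawing
#'
#' @param drawing A [BodyDrawing-class].
#' @param spec A [SymptomSpec-class].
#' @param maps Named list of [SymptomMap-class] objects; views not supplied
#'   are filled with blank maps.
#' @return The extended drawing.
#' @export
addSymptom <- function(drawing, spec, maps = list()) {
  stopifnot(is(drawing, "BodyDrawing"), is(spec, "SymptomSpec"))
  dims <- drawing@outlines@dims
  full <- lapply(bodyViews(), function(v)
    if (!is.null(maps[[v]])) maps[[v]] else blankMap(v, dims))
  names(full) <- bodyViews()
  drawing@symptoms <- c(drawing@symptoms,
                        list(list(spec = spec, maps = full)))
  validObject(drawing)
  drawing
}

#' Accessors for BodyDrawing
#'
#' @param x A [BodyDrawing-class].
#' @return `patientId()`: the patient identifier; `session()` the session
#'   label; `outlineGender()` the chosen outline gender; `outlines()` the
#'   [OutlineSet-class]; `symptoms()` the symptom list.
#' @name drawing-accessors
NULL

#' @rdname drawing-accessors
#' @export
patientId <- function(x) { stopifnot(is(x, "BodyDrawing")); x@patientId }

#' @rdname drawing-accessors
#' @export
session <- function(x) { stopifnot(is(x, "BodyDrawing")); x@session }

#' @rdname drawing-accessors
#' @export
outlineGender <- function(x) { stopifnot(is(x, "BodyDrawing")); x@outlineGender }

#' @rdname drawing-accessors
#' @export
outlines <- function(x) { stopifnot(is(x, "BodyDrawing")); x@outlines }

#' @rdname drawing-accessors
#' @export
symptoms <- function(x) { stopifnot(is(x, "BodyDrawing")); x@symptoms }

#' Validate a drawing against the domain rules
#'
#' Checks every rule the acquisition app enforces at source, so drawings
#' from other provenances can be audited: nonzero ink must lie inside the
#' body outline, all VAS values must be in 0..10 with `vasMin <= vasMax`,
#' and every symptom needs at least one descriptor. Violations are reported,
#' never silently repaired; a conformant drawing yields a zero-row report.
#' The function is read-only and idempotent.
#'
#' @param d A [BodyDrawing-class].
#' @return A data.frame with columns `symptom` (index or NA), `view`
#'   (or NA), `rule`, `detail`; zero rows when the drawing is valid.
#' @export
validateDrawing <- function(d) {
  stopifnot(is(d, "BodyDrawing"))
  rows <- list()
  add <- function(symptom, view, rule, detail)
    rows[[length(rows) + 1L]] <<- data.frame(
      symptom = symptom, view = view, rule = rule, detail = detail,
      stringsAsFactors = FALSE)
  for (i in seq_along(d@symptoms)) {
    s <- d@symptoms[[i]]
    sp <- s$spec
    if (!length(sp@descriptors))
      add(i, NA_character_, "empty_descriptors", "no sensation descriptor")
    for (f in c("vasMax", "vasMin", "burden")) {
      v <- slot(sp, f)
      if (is.na(v) || v < 0L || v > 10L)
        add(i, NA_character_, "vas_out_of_range",
            sprintf("%s = %s", f, v))
    }
    if (!is.na(sp@vasMin) && !is.na(sp@vasMax) && sp@vasMin > sp@vasMax)
      add(i, NA_character_, "vas_min_exceeds_max",
          sprintf("vasMin %d > vasMax %d", sp@vasMin, sp@vasMax))
    for (v in bodyViews()) {
      m <- s$maps[[v]]@intensities
      out <- sum(m > 0L & !d@outlines@masks[[v]])
      if (out > 0L)
        add(i, v, "ink_outside_outline",
            sprintf("%d nonzero pixel(s) outside the outline", out))
      if (any(m < 0L | m > 10L))
        add(i, v, "intensity_out_of_range", "pixel VAS outside 0..10")
    }
  }
  if (!length(rows))
    return(data.frame(symptom = integer(0), view = character(0),
                      rule = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

setMethod("show", "OutlineSet", function(object) {
  cat(sprintf("OutlineSet: %d x %d px, views %s\n",
              object@dims[1L], object@dims[2L],
              paste(names(object@masks), collapse = "/")))
  fr <- vapply(object@masks, function(m) mean(m), numeric(1))
  cat(sprintf("  interior fraction: %s\n",
              paste(sprintf("%s %.2f", names(fr), fr), collapse = ", ")))
})

setMethod("show", "SymptomMap", function(object) {
  cat(sprintf("SymptomMap [%s]: %d x %d px, %d drawn pixel(s), max VAS %d\n",
              object@view, nrow(object@intensities), ncol(object@intensities),
              sum(object@intensities > 0L), max(object@intensities, 0L)))
})

setMethod("show", "MergedMap", function(object) {
  cat(sprintf("MergedMap [%s]: %d x %d px, %d symptom(s), %d drawn pixel(s)\n",
              object@view, nrow(object@intensities), ncol(object@intensities),
              object@nSymptoms, sum(object@intensities > 0L)))
})

setMethod("show", "BodyDrawing", function(object) {
  cat(sprintf("BodyDrawing: patient %s, session %s, outline %s (%d x %d px)\n",
              object@patientId, object@session, object@outlineGender,
              object@outlines@dims[1L], object@outlines@dims[2L]))
  cat(sprintf("  %d symptom(s)\n", length(object@symptoms)))
})

setMethod("show", "SymptomSpec", function(object) {
  cat(sprintf("SymptomSpec: %s; depth %s; VAS %d-%d; burden %d\n",
              paste(object@descriptors, collapse = ", "),
              paste(object@depths, collapse = ", "),
              object@vasMin, object@vasMax, object@burden))
})
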