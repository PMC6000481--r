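# VAS <-> 8-bit grayscale PNG level. round(255 * v / 10) is invertible by
# nearest-level decoding, so the round trip is lossless.
.vasToLevel <- function(v) {
  l <- round(255 * v / 10); storage.mode(l) <- "integer"; l
}
.levelToVas <- function(l) {
  v <- round(10 * l / 255); storage.mode(v) <- "integer"; v
}

.writeMaskPNG <- function(mask, path)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)

.writeVasPNG <- function(m, path)
  png::writePNG(.vasToLevel(m) / 255, path)

#' Read a symptom-map PNG
#'
#' Two encodings are supported. `"grayscale"` is this package's lossless
#' dialect: single channel, level `round(255 * VAS / 10)`, decoded by
#' nearest VAS level. `"saturation"` decodes app-exported colour drawings in
#' which intensity was encoded as colour saturation: the HSV saturation of
#' each non-background pixel is passed through `transfer` (a configurable
#' saturation-to-fraction curve, identity by default) and scaled to VAS
#' 0..10.
#'
#' @param path PNG file.
#' @param view Body view to label the map with.
#' @param encoding `"grayscale"` (default) or `"saturation"`.
#' @param transfer Monotone function mapping saturation in `[0, 1]` to a VAS
#'   fraction in `[0, 1]`; used only by the saturation decoder.
#' @return A [SymptomMap-class].
#' @export
readSymptomPNG <- function(path, view, encoding = c("grayscale",
                                                    "saturation"),
                           transfer = identity) {
  encoding <- match.arg(encoding)
  img <- png::readPNG(path)
  if (encoding == "grayscale") {
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    vas <- .levelToVas(round(img * 255))
  } else {
    if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
      stop("saturation decoding needs an RGB image")
    r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
    mx <- pmax(r, g, b); mn <- pmin(r, g, b)
    sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
    vas <- vasRound(10 * transfer(sat))
    vas[mx == 0] <- 0L
  }
  symptomMap(view, matrix(as.integer(vas), nrow(img), ncol(img)))
}

.specsToDF <- function(specs) {
  do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(symptom = i,
               descriptors = paste(s@descriptors, collapse = "|"),
               depths = paste(s@depths, collapse = "|"),
               vasMax = s@vasMax, vasMin = s@vasMin,
               currentlyPresent = s@currentlyPresent,
               worstInterval = s@worstInterval, burden = s@burden,
               stringsAsFactors = FALSE)
  }))
}

.specsFromDF <- function(d) {
  lapply(seq_len(nrow(d)), function(i)
    symptomSpec(descriptors = strsplit(d$descriptors[i], "|",
                                       fixed = TRUE)[[1L]],
                depths = strsplit(d$depths[i], "|", fixed = TRUE)[[1L]],
                vasMax = d$vasMax[i], vasMin = d$vasMin[i],
                currentlyPresent = d$currentlyPresent[i],
                worstInterval = d$worstInterval[i], burden = d$burden[i]))
}

#' Write a drawing to disk
#'
#' Serializes one acquisition session as the package's file layout: one
#' grayscale PNG per symptom and view (`symptom<i>_<view>.png`, lossless VAS
#' encoding), one binary PNG per outline view (`outline_<view>.png`), the
#' symptom specifications as both CSV (`symptoms.csv`, one row per symptom,
#' list fields `|`-delimited) and JSON inside the manifest
#' (`manifest.json`, which also records patient id, session, outline gender
#' and raster dims).
#'
#' @param d A [BodyDrawing-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @seealso [readDrawing()] for the lossless inverse.
#' @export
writeDrawing <- function(d, dir) {
  stopifnot(is(d, "BodyDrawing"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in bodyViews())
    .writeMaskPNG(d@outlines@masks[[v]],
                  file.path(dir, sprintf("outline_%s.png", v)))
  for (i in seq_along(d@symptoms))
    for (v in bodyViews())
      .writeVasPNG(d@symptoms[[i]]$maps[[v]]@intensities,
                   file.path(dir, sprintf("symptom%d_%s.png", i, v)))
  specs <- lapply(d@symptoms, `[[`, "spec")
  specDF <- .specsToDF(specs)
  if (!is.null(specDF))
    utils::write.csv(specDF, file.path(dir, "symptoms.csv"),
                     row.names = FALSE)
  manifest <- list(patientId = d@patientId, session = d@session,
                   outlineGender = d@outlineGender,
                   dims = as.integer(d@outlines@dims),
                   nSymptoms = length(d@symptoms),
                   views = bodyViews(),
                   symptoms = if (is.null(specDF)) list() else specDF)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a drawing from disk
#'
#' Inverse of [writeDrawing()]; the round trip is lossless pixel-for-pixel
#' and spec-for-spec. Raster dimensions are checked against the manifest and
#' the outline masks; mismatches and missing files are errors.
#'
#' @param dir Directory written by [writeDrawing()].
#' @return A [BodyDrawing-class].
#' @export
readDrawing <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  dims <- as.integer(man$dims)
  masks <- lapply(bodyViews(), function(v) {
    f <- file.path(dir, sprintf("outline_%s.png", v))
    if (!file.exists(f)) stop("missing outline file: ", f)
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (!identical(dim(img), dims))
      stop("outline '", v, "' does not match manifest dims")
    img > 0.5
  })
  names(masks) <- bodyViews()
  ol <- outlineSet(masks)
  n <- as.integer(man$nSymptoms)
  specs <- if (n > 0L)
    .specsFromDF(utils::read.csv(file.path(dir, "symptoms.csv"),
                                 stringsAsFactors = FALSE))
  else list()
  symptomsList <- lapply(seq_len(n), function(i) {
    maps <- lapply(bodyViews(), function(v) {
      f <- file.path(dir, sprintf("symptom%d_%s.png", i, v))
      if (!file.exists(f)) stop("missing symptom map: ", f)
      m <- readSymptomPNG(f, v)
      if (!identical(dim(m@intensities), dims))
        stop("symptom map '", basename(f), "' does not match manifest dims")
      m
    })
    names(maps) <- bodyViews()
    list(spec = specs[[i]], maps = maps)
  })
  bodyDrawing(man$patientId, man$session, ol, symptomsList,
              man$outlineGender)
}

#' Write a synthetic cohort to disk
#'
#' One directory per patient with `test/` and `retest/` drawing file sets
#' (see [writeDrawing()]), so simulated and real data share one layout.
#'
#' @param cohort Result of [generateCohort()].
#' @param dir Output directory.
#' @return Invisibly, the patient directories.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- vapply(cohort, function(pair) {
    pd <- file.path(dir, pair$test@patientId)
    writeDrawing(pair$test, file.path(pd, "test"))
    writeDrawing(pair$retest, file.path(pd, "retest"))
    pd
  }, character(1))
  invisible(dirs)
}

#' Read a cohort of test-retest pairs from disk
#'
#' @param dir Directory with one subdirectory per patient, each holding
#'   `test/` and `retest/` drawing file sets.
#' @return List of `list(test = , retest = )` pairs.
#' @export
readCohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory does not exist: ", dir)
  pds <- list.dirs(dir, recursive = FALSE)
  pds <- pds[file.exists(file.path(pds, "test", "manifest.json"))]
  if (!length(pds))
    stop("no test-retest drawing pairs found in ", dir)
  lapply(pds, function(pd)
    list(test = readDrawing(file.path(pd, "test")),
         retest = readDrawing(file.path(pd, "retest"))))
}

#' Export a map as a single-slice NIfTI volume
#'
#' Writes the raster as a rows x cols x 1 volume with an identity affine
#' and nominal 1 mm isotropic spacing: the format is a carrier for
#' cluster-tool interoperability, not a spatial claim. The number of voxels
#' with value > 0 equals the symptom extent of the map.
#'
#' @param map A [SymptomMap-class], [MergedMap-class], logical mask or
#'   integer matrix.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
exportNifti <- function(map, path) {
  m <- if (is.matrix(map)) map else intensities(map)
  vol <- array(as.numeric(m), dim = c(dim(m), 1L))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Read back a single-slice NIfTI volume as a matrix
#'
#' @param path NIfTI file written by [exportNifti()].
#' @return Integer matrix.
#' @export
readNiftiMap <- function(path) {
  m <- as.array(RNifti::readNifti(path))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}
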