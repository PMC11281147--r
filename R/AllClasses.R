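## Central S4 classes. Images are integer arrays [height, width, 3] with
## intensities in 0..255; boxes are data.frames in normalized YOLO
## center-size convention.

.PROVENANCE_LEVELS <- c("original", "gamma", "brightness_contrast", "noise",
                        "translation", "rotation", "mosaic", "modified_mosaic")

.AUG_METHODS <- c("gamma", "brightness_contrast", "noise",
                  "translation", "rotation", "mosaic", "modified_mosaic")

#' Construct a ground-truth box table
#'
#' Builds the canonical box container used throughout the package: a
#' data.frame with columns `class_id`, `cx`, `cy`, `w`, `h`, all box
#' coordinates normalized to image width/height (YOLO convention).
#'
#' @param class_id integer vector of non-negative class labels.
#' @param cx,cy box-center coordinates as fractions of image width/height,
#'   in (0, 1).
#' @param w,h box extents as fractions of image width/height, in (0, 1].
#' @return a validated data.frame with one row per box.
#' @examples
#' yoloBoxes(0L, 0.5, 0.5, 0.2, 0.1)
#' @export
yoloBoxes <- function(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()) {
  df <- data.frame(class_id = as.integer(class_id),
                   cx = as.numeric(cx), cy = as.numeric(cy),
                   w = as.numeric(w), h = as.numeric(h))
  validateBoxes(df)
  df
}

#' Construct a detection table
#'
#' Like [yoloBoxes()] with an additional `confidence` column in \[0, 1\].
#'
#' @inheritParams yoloBoxes
#' @param confidence detector confidence scores in \[0, 1\].
#' @return a validated data.frame with one row per detection.
#' @export
yoloDetections <- function(class_id = integer(), cx = numeric(),
                           cy = numeric(), w = numeric(), h = numeric(),
                           confidence = numeric()) {
  df <- data.frame(class_id = as.integer(class_id),
                   cx = as.numeric(cx), cy = as.numeric(cy),
                   w = as.numeric(w), h = as.numeric(h),
                   confidence = as.numeric(confidence))
  validateBoxes(df, detection = TRUE)
  df
}

#' Validate a box or detection table
#'
#' Checks the normalized-coordinate invariants: centers in (0,1), extents in
#' (0,1], box span within \[0,1\], non-negative integer classes, and (for
#' detections) confidences in \[0,1\]. Called by every operator that accepts
#' external boxes.
#'
#' @param boxes data.frame as produced by [yoloBoxes()] or [yoloDetections()].
#' @param detection logical; require and check a `confidence` column.
#' @param tol numeric slack on the containment checks.
#' @return invisibly `TRUE`; otherwise an error.
#' @export
validateBoxes <- function(boxes, detection = FALSE, tol = 1e-9) {
  need <- c("class_id", "cx", "cy", "w", "h")
  if (detection) need <- c(need, "confidence")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop("boxes must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(boxes) == 0L) return(invisible(TRUE))
  with(boxes, {
    if (any(class_id < 0L)) stop("class_id must be non-negative", call. = FALSE)
    if (any(w <= 0) || any(h <= 0))
      stop("box width and height must be positive", call. = FALSE)
    if (any(cx - w / 2 < -tol) || any(cx + w / 2 > 1 + tol) ||
        any(cy - h / 2 < -tol) || any(cy + h / 2 > 1 + tol))
      stop("box extends outside the unit square", call. = FALSE)
    if (detection && (any(confidence < 0) || any(confidence > 1)))
      stop("confidence must lie in [0, 1]", call. = FALSE)
  })
  invisible(TRUE)
}

setClassUnion("listOrNULL", c("list", "NULL"))

#' AnnotatedImage: an RGB raster with its ground-truth boxes
#'
#' The unit flowing through every augmentation operator. The raster is an
#' integer array `[height, width, 3]` with intensities in 0..255; boxes use
#' the normalized YOLO convention. `provenance` records which operator (if
#' any) produced the image; `meta` carries the sampled parameters and source
#' ids written to enrichment manifests.
#'
#' @slot image integer array `[height, width, 3]`, values in 0..255,
#'   both spatial dimensions at least 8.
#' @slot boxes data.frame of ground-truth boxes (see [yoloBoxes()]).
#' @slot id opaque image identifier, unique within a dataset.
#' @slot provenance one of `original`, `gamma`, `brightness_contrast`,
#'   `noise`, `translation`, `rotation`, `mosaic`, `modified_mosaic`.
#' @slot meta free-form list of provenance details (sampled parameters,
#'   source image ids).
#' @export
setClass("AnnotatedImage",
         representation(image = "array", boxes = "data.frame",
                        id = "character", provenance = "character",
                        meta = "list"),
         prototype(boxes = yoloBoxes(), id = "img",
                   provenance = "original", meta = list()))

setValidity("AnnotatedImage", function(object) {
  img <- object@image
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L)
    return("image must be a [height, width, 3] array")
  if (d[1L] < 8L || d[2L] < 8L)
    return("image must be at least 8x8 pixels")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    return("intensities must lie in [0, 255]")
  if (any(img != floor(img)))
    return("intensities must be integer-valued")
  ok <- tryCatch({ validateBoxes(object@boxes); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  if (length(object@id) != 1L || !nzchar(object@id))
    return("id must be a single non-empty string")
  if (!object@provenance %in% .PROVENANCE_LEVELS)
    return(paste("provenance must be one of:",
                 paste(.PROVENANCE_LEVELS, collapse = ", ")))
  TRUE
})

#' Create an AnnotatedImage
#'
#' @param image numeric array `[height, width, 3]` with values in 0..255
#'   (coerced to storage mode integer-valued double).
#' @param boxes data.frame of boxes, default none.
#' @param id image identifier.
#' @param provenance provenance tag, default `"original"`.
#' @param meta list of provenance details.
#' @return an [AnnotatedImage-class] object.
#' @examples
#' img <- AnnotatedImage(array(128, dim = c(16, 16, 3)), id = "ex")
#' nBoxes(img)
#' @export
AnnotatedImage <- function(image, boxes = yoloBoxes(), id = "img",
                           provenance = "original", meta = list()) {
  storage.mode(image) <- "double"
  new("AnnotatedImage", image = image, boxes = boxes, id = id,
      provenance = provenance, meta = meta)
}

#' EnrichmentPlan: a deterministic dataset-expansion recipe
#'
#' @slot methods distinct method names among `gamma`, `brightness_contrast`,
#'   `noise`, `translation`, `rotation`, `mosaic`, `modified_mosaic`.
#' @slot multiple positive integer: augmented copies of the original set per
#'   method.
#' @slot seed master random seed controlling every sampled parameter.
#' @slot includeOriginals whether the originals are carried into the output.
#' @export
setClass("EnrichmentPlan",
         representation(methods = "character", multiple = "integer",
                        seed = "integer", includeOriginals = "logical"),
         prototype(multiple = 1L, seed = 1L, includeOriginals = TRUE))

setValidity("EnrichmentPlan", function(object) {
  m <- object@methods
  if (length(m) == 0L) return("methods must be non-empty")
  if (anyDuplicated(m)) return("methods must be distinct")
  bad <- setdiff(m, .AUG_METHODS)
  if (length(bad))
    return(paste("unknown methods:", paste(bad, collapse = ", ")))
  if (length(object@multiple) != 1L || object@multiple < 1L)
    return("multiple must be a positive integer")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  if (length(object@includeOriginals) != 1L)
    return("includeOriginals must be a single logical")
  TRUE
})

#' Create an EnrichmentPlan
#'
#' @param methods character vector of augmentation method names.
#' @param multiple positive integer `k`: each method contributes `k` full
#'   passes over the original set.
#' @param seed master seed; identical plans give byte-identical outputs.
#' @param includeOriginals carry the originals into the enriched set
#'   (default `TRUE`, the usual training protocol).
#' @return an [EnrichmentPlan-class] object.
#' @examples
#' EnrichmentPlan(c("gamma", "brightness_contrast"), multiple = 1, seed = 7)
#' @export
EnrichmentPlan <- function(methods, multiple = 1L, seed = 1L,
                           includeOriginals = TRUE) {
  new("EnrichmentPlan", methods = as.character(methods),
      multiple = as.integer(multiple), seed = as.integer(seed),
      includeOriginals = isTRUE(includeOriginals))
}

#' EvalResult: per-class average precision and the two headline means
#'
#' @slot ap numeric matrix of AP values, classes in rows, IoU thresholds in
#'   columns.
#' @slot map50 mean over classes of AP at IoU 0.5.
#' @slot map50_95 mean over classes and the thresholds 0.50, 0.55, ..., 0.95.
#' @slot thresholds the IoU thresholds evaluated.
#' @slot curves list (by class) of precision-recall data.frames at the first
#'   threshold.
#' @export
setClass("EvalResult",
         representation(ap = "matrix", map50 = "numeric",
                        map50_95 = "numeric", thresholds = "numeric",
                        curves = "list"))

setValidity("EvalResult", function(object) {
  if (length(object@map50) != 1L || length(object@map50_95) != 1L)
    return("map50 and map50_95 must be single values")
  if (!is.na(object@map50) &&
      (object@map50 < -1e-12 || object@map50 > 1 + 1e-12))
    return("map50 must lie in [0, 1]")
  if (!is.na(object@map50) && !is.na(object@map50_95) &&
      object@map50_95 > object@map50 + 1e-9)
    return("map50_95 cannot exceed map50")
  TRUE
})

#' SynthConfig: parameters of the synthetic trap-image generator
#'
#' Describes a sticky-paper trap photograph: a bright, subtly textured paper
#' with a linear illumination gradient, carrying small dark elliptical
#' insects at known positions.
#'
#' @slot imageSize square image side in pixels.
#' @slot nInsects integer range (min, max) of insects per image.
#' @slot insectAxes pixel range (min, max) for ellipse semi-axes; the
#'   largest axis must not exceed `imageSize / 6` (small-object regime).
#' @slot backgroundLevel intensity range of the paper surface.
#' @slot gradientStrength intensity span of the illumination ramp.
#' @slot textureStd standard deviation of the paper-texture noise.
#' @export
setClass("SynthConfig",
         representation(imageSize = "integer", nInsects = "integer",
                        insectAxes = "numeric", backgroundLevel = "numeric",
                        gradientStrength = "numeric", textureStd = "numeric"),
         prototype(imageSize = 320L, nInsects = c(3L, 12L),
                   insectAxes = c(4, 14), backgroundLevel = c(190, 225),
                   gradientStrength = 35, textureStd = 6))

setValidity("SynthConfig", function(object) {
  if (object@imageSize < 8L) return("imageSize must be at least 8")
  if (length(object@nInsects) != 2L || any(object@nInsects < 0L) ||
      object@nInsects[1L] > object@nInsects[2L])
    return("nInsects must be a non-negative (min, max) range")
  if (length(object@insectAxes) != 2L || any(object@insectAxes <= 0) ||
      object@insectAxes[1L] > object@insectAxes[2L])
    return("insectAxes must be a positive (min, max) range")
  if (object@insectAxes[2L] > object@imageSize / 6)
    return("largest insect axis must not exceed imageSize / 6")
  if (length(object@backgroundLevel) != 2L ||
      object@backgroundLevel[1L] > object@backgroundLevel[2L])
    return("backgroundLevel must be a (min, max) range")
  if (object@backgroundLevel[1L] < 0 ||
      object@backgroundLevel[2L] + object@gradientStrength / 2 > 255)
    return("background plus gradient must stay within [0, 255]")
  if (object@textureStd < 0) return("textureStd must be non-negative")
  TRUE
})

#' Create a SynthConfig
#'
#' @param imageSize square image side in pixels (default 320).
#' @param nInsects integer range (min, max) of insects per image.
#' @param insectAxes pixel range for ellipse semi-axes.
#' @param backgroundLevel intensity range for the paper surface.
#' @param gradientStrength intensity span of the illumination ramp.
#' @param textureStd paper-texture noise standard deviation.
#' @return a [SynthConfig-class] object.
#' @examples
#' SynthConfig(imageSize = 96, nInsects = c(2, 6), insectAxes = c(3, 8))
#' @export
SynthConfig <- function(imageSize = 320L, nInsects = c(3L, 12L),
                        insectAxes = c(4, 14), backgroundLevel = c(190, 225),
                        gradientStrength = 35, textureStd = 6) {
  new("SynthConfig", imageSize = as.integer(imageSize),
      nInsects = as.integer(nInsects), insectAxes = as.numeric(insectAxes),
      backgroundLevel = as.numeric(backgroundLevel),
      gradientStrength = as.numeric(gradientStrength),
      textureStd = as.numeric(textureStd))
}
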