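#' @rdname trapaug-accessors
#' @aliases imageArray,AnnotatedImage-method
setMethod("imageArray", "AnnotatedImage", function(x) x@image)

#' @rdname trapaug-accessors
#' @aliases boxes,AnnotatedImage-method
setMethod("boxes", "AnnotatedImage", function(x) x@boxes)

#' @rdname trapaug-accessors
#' @aliases boxes<-,AnnotatedImage-method
setReplaceMethod("boxes", "AnnotatedImage", function(x, value) {
  x@boxes <- value
  validObject(x)
  x
})

#' @rdname trapaug-accessors
#' @aliases imageId,AnnotatedImage-method
setMethod("imageId", "AnnotatedImage", function(x) x@id)

#' @rdname trapaug-accessors
#' @aliases imageId<-,AnnotatedImage-method
setReplaceMethod("imageId", "AnnotatedImage", function(x, value) {
  x@id <- as.character(value)
  validObject(x)
  x
})

#' @rdname trapaug-accessors
#' @aliases provenance,AnnotatedImage-method
setMethod("provenance", "AnnotatedImage", function(x) x@provenance)

#' @rdname trapaug-accessors
#' @aliases imageMeta,AnnotatedImage-method
setMethod("imageMeta", "AnnotatedImage", function(x) x@meta)

#' @rdname trapaug-accessors
#' @aliases nBoxes,AnnotatedImage-method
setMethod("nBoxes", "AnnotatedImage", function(x) nrow(x@boxes))

#' @describeIn AnnotatedImage image dimensions as `c(height, width)`.
#' @param x an `AnnotatedImage`.
#' @export
setMethod("dim", "AnnotatedImage", function(x) dim(x@image)[1:2])

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("AnnotatedImage '%s' [%s]\n", object@id, object@provenance))
  cat(sprintf("  raster: %d x %d x %d, intensities %d..%d\n",
              d[1L], d[2L], d[3L],
              as.integer(min(object@image)), as.integer(max(object@image))))
  cat(sprintf("  boxes:  %d (classes: %s)\n", nrow(object@boxes),
              if (nrow(object@boxes)) paste(sort(unique(object@boxes$class_id)),
                                            collapse = ", ") else "-"))
})

setMethod("show", "EnrichmentPlan", function(object) {
  cat("EnrichmentPlan\n")
  cat("  methods:          ", paste(object@methods, collapse = ", "), "\n")
  cat("  multiple:         ", object@multiple, "\n")
  cat("  seed:             ", object@seed, "\n")
  cat("  includeOriginals: ", object@includeOriginals, "\n")
})

#' @rdname trapaug-accessors
#' @aliases apValues,EvalResult-method
setMethod("apValues", "EvalResult", function(x) x@ap)

#' @rdname trapaug-accessors
#' @aliases mAP50,EvalResult-method
setMethod("mAP50", "EvalResult", function(x) x@map50)

#' @rdname trapaug-accessors
#' @aliases mAP50_95,EvalResult-method
setMethod("mAP50_95", "EvalResult", function(x) x@map50_95)

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult\n")
  cat(sprintf("  classes:   %d\n", nrow(object@ap)))
  cat(sprintf("  IoU sweep: %s\n",
              paste(format(object@thresholds), collapse = " ")))
  cat(sprintf("  mAP50:     %.4f\n", object@map50))
  cat(sprintf("  mAP50-95:  %.4f\n", object@map50_95))
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig\n")
  cat(sprintf("  image:      %d x %d px\n", object@imageSize, object@imageSize))
  cat(sprintf("  insects:    %d..%d per image, semi-axes %.1f..%.1f px\n",
              object@nInsects[1L], object@nInsects[2L],
              object@insectAxes[1L], object@insectAxes[2L]))
  cat(sprintf("  background: %.0f..%.0f, gradient span %.0f, texture sd %.1f\n",
              object@backgroundLevel[1L], object@backgroundLevel[2L],
              object@gradientStrength, object@textureStd))
})
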