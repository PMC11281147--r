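#' @name trapaug-accessors
#' @title Accessors for trapaug classes
#' @description Slot accessors for [AnnotatedImage-class],
#'   [EnrichmentPlan-class] and [EvalResult-class] objects.
#' @param x an object.
#' @param value replacement value.
NULL

#' @rdname trapaug-accessors
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))

#' @rdname trapaug-accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))

#' @rdname trapaug-accessors
#' @export
setGeneric("boxes<-", function(x, value) standardGeneric("boxes<-"))

#' @rdname trapaug-accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname trapaug-accessors
#' @export
setGeneric("imageId<-", function(x, value) standardGeneric("imageId<-"))

#' @rdname trapaug-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname trapaug-accessors
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))

#' @rdname trapaug-accessors
#' @export
setGeneric("nBoxes", function(x) standardGeneric("nBoxes"))

#' @rdname trapaug-accessors
#' @export
setGeneric("apValues", function(x) standardGeneric("apValues"))

#' @rdname trapaug-accessors
#' @export
setGeneric("mAP50", function(x) standardGeneric("mAP50"))

#' @rdname trapaug-accessors
#' @export
setGeneric("mAP50_95", function(x) standardGeneric("mAP50_95"))
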