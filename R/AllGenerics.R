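#' Accessors for IrisPheno S4 objects
#'
#' Small accessor generics: `pixelArray` returns the `H x W x 3` integer
#' pixel array of an [EyeImage-class]; `sampleId` its identifier;
#' `imageDim` the (rows, cols) dimensions; `edgePixels` the logical edge
#' mask of an [EdgeMap-class]; `irisMask` the annulus mask, `limbus` and
#' `pupil` the fitted circles and `isCurated` the manual-override flag of
#' an [IrisSegmentation-class].
#'
#' @param object an IrisPheno S4 object.
#' @return The slot value (see description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelArray", function(object) standardGeneric("pixelArray"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("imageDim", function(object) standardGeneric("imageDim"))
#' @rdname accessors
#' @export
setGeneric("edgePixels", function(object) standardGeneric("edgePixels"))
#' @rdname accessors
#' @export
setGeneric("irisMask", function(object) standardGeneric("irisMask"))
#' @rdname accessors
#' @export
setGeneric("limbus", function(object) standardGeneric("limbus"))
#' @rdname accessors
#' @export
setGeneric("pupil", function(object) standardGeneric("pupil"))
#' @rdname accessors
#' @export
setGeneric("isCurated", function(object) standardGeneric("isCurated"))

#' @rdname accessors
setMethod("pixelArray", "EyeImage", function(object) object@pixels)
#' @rdname accessors
setMethod("sampleId", "EyeImage", function(object) object@sampleId)
#' @rdname accessors
setMethod("imageDim", "EyeImage", function(object) dim(object@pixels)[1:2])
#' @rdname accessors
setMethod("edgePixels", "EdgeMap", function(object) object@edges)
#' @rdname accessors
setMethod("irisMask", "IrisSegmentation", function(object) object@mask)
#' @rdname accessors
setMethod("limbus", "IrisSegmentation", function(object) object@limbus)
#' @rdname accessors
setMethod("pupil", "IrisSegmentation", function(object) object@pupil)
#' @rdname accessors
setMethod("isCurated", "IrisSegmentation", function(object) object@curated)

setMethod("show", "EyeImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("EyeImage '%s' (%d x %d, 8-bit RGB, source: %s)\n",
              object@sampleId, d[1L], d[2L], object@source))
})

setMethod("show", "EdgeMap", function(object) {
  cat(sprintf("EdgeMap %d x %d with %d edge pixels\n",
              nrow(object@edges), ncol(object@edges), sum(object@edges)))
})

setMethod("show", "Circle", function(object) {
  cat(sprintf(
    "Circle: centre (%.1f, %.1f), radius %.1f px, score %.0f\n",
    object@centerRow, object@centerCol, object@radius, object@score))
})

setMethod("show", "IrisSegmentation", function(object) {
  cat(sprintf(
    "IrisSegmentation%s: limbus r=%.1f at (%.1f, %.1f), pupil r=%.1f, %d iris pixels\n",
    if (object@curated) " (curated)" else "",
    object@limbus@radius, object@limbus@centerRow, object@limbus@centerCol,
    object@pupil@radius, sum(object@mask)))
})

setMethod("show", "PigmentClassifier", function(object) {
  cat(sprintf(
    "PigmentClassifier (quadratic-kernel SVM, %s features, %d training pixels)\n",
    object@encoding, nrow(object@training$pixels)))
  cat(sprintf("  gamma=%g coef0=%g cost=%g, classes: %s\n",
              object@gamma, object@coef0, object@cost,
              paste(object@classes, collapse = ", ")))
})
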