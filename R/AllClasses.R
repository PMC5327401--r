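#' @import methods
NULL

#' EyeImage: an 8-bit RGB eye photograph
#'
#' Container for a digital eye photograph on which iris segmentation and
#' pigmentation quantification operate. Pixels are stored as an
#' `H x W x 3` integer array with channel values in `[0, 255]`.
#'
#' @slot pixels integer array of dimension `H x W x 3` (rows, columns,
#'   RGB channels), values in `[0, 255]`.
#' @slot sampleId character scalar identifying the eye/sample.
#' @slot source character scalar: originating file path or `"synthetic"`.
#'
#' @seealso [readEyeImage()], [renderSyntheticEye()]
#' @exportClass EyeImage
setClass("EyeImage",
  representation(pixels = "array", sampleId = "character",
                 source = "character"))

setValidity("EyeImage", function(object) {
  p <- object@pixels
  d <- dim(p)
  if (length(d) != 3L || d[3L] != 3L)
    return("pixels must be an H x W x 3 array")
  if (d[1L] < 64L || d[2L] < 64L)
    return(sprintf("image too small (%dx%d); at least 64x64 required",
                   d[1L], d[2L]))
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("channel values must lie in [0, 255]")
  if (length(object@sampleId) != 1L) return("sampleId must be a scalar")
  TRUE
})

#' EdgeMap: Canny edge detection result
#'
#' Boolean edge mask plus the gradient-magnitude image it was derived from,
#' both with the dimensions of the source image.
#'
#' @slot edges logical `H x W` matrix, `TRUE` at edge pixels.
#' @slot gradientMagnitude numeric `H x W` matrix of non-negative gradient
#'   magnitudes of the smoothed luminance image.
#'
#' @seealso [detectEdges()], [findCircles()]
#' @exportClass EdgeMap
setClass("EdgeMap",
  representation(edges = "matrix", gradientMagnitude = "matrix"))

setValidity("EdgeMap", function(object) {
  if (!identical(dim(object@edges), dim(object@gradientMagnitude)))
    return("edges and gradientMagnitude must have identical dimensions")
  if (!is.logical(object@edges)) return("edges must be logical")
  if (any(object@gradientMagnitude < 0)) return("gradient must be >= 0")
  if (any(object@edges & object@gradientMagnitude <= 0))
    return("edge pixels must have positive gradient magnitude")
  TRUE
})

#' Circle: a circle candidate from the Hough transform
#'
#' Centre coordinates are real-valued in the 0-based (row, col) pixel frame;
#' `score` counts accumulator votes (edge pixels supporting the circle).
#'
#' @slot centerRow,centerCol numeric scalars, circle centre in pixels.
#' @slot radius positive numeric scalar, radius in pixels.
#' @slot score non-negative numeric scalar, Hough accumulator votes.
#'
#' @seealso [findCircles()], [segmentIris()]
#' @exportClass Circle
setClass("Circle",
  representation(centerRow = "numeric", centerCol = "numeric",
                 radius = "numeric", score = "numeric"))

setValidity("Circle", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (object@score < 0) return("score must be non-negative")
  TRUE
})

#' IrisSegmentation: detected iris annulus
#'
#' Holds the detected limbus (outer) and pupil (inner) circles together with
#' the boolean annulus mask on which every colour quantity is computed. The
#' mask is `TRUE` exactly for pixels whose distance `d` from the limbus
#' centre satisfies `pupil radius < d <= limbus radius`.
#'
#' @slot limbus,pupil [Circle-class] objects; the pupil radius is strictly
#'   smaller than the limbus radius.
#' @slot mask logical `H x W` matrix (the iris annulus), covering at least
#'   5\% of the image area.
#' @slot curated logical flag: `TRUE` when the circles were supplied by
#'   manual override rather than detected automatically.
#'
#' @seealso [segmentIris()], [overrideSegmentation()], [applyMask()]
#' @exportClass IrisSegmentation
setClass("IrisSegmentation",
  representation(limbus = "Circle", pupil = "Circle", mask = "matrix",
                 curated = "logical"))

setValidity("IrisSegmentation", function(object) {
  if (object@pupil@radius >= object@limbus@radius)
    return("pupil radius must be smaller than limbus radius")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (mean(object@mask) < 0.05)
    return("mask covers less than 5% of the image area")
  d <- dim(object@mask)
  rr <- matrix(seq_len(d[1L]) - 1, d[1L], d[2L])
  cc <- matrix(seq_len(d[2L]) - 1, d[1L], d[2L], byrow = TRUE)
  dist <- sqrt((rr - object@limbus@centerRow)^2 +
               (cc - object@limbus@centerCol)^2)
  ok <- dist > object@pupil@radius & dist <= object@limbus@radius
  if (any(object@mask & !ok))
    return("mask extends outside the limbus/pupil annulus")
  TRUE
})

#' PigmentClassifier: 3-class SVM pixel classifier
#'
#' A one-vs-one soft-margin support vector machine with quadratic
#' (degree-2 polynomial) kernel `K(x, y) = (gamma * x.y + coef0)^2`,
#' assigning each iris pixel in HSV space to one of `non_pigmented`,
#' `pheomelanin` or `eumelanin`. The training pixels are retained so the
#' model can be serialized as plain JSON and refitted bit-identically.
#'
#' @slot model the fitted [e1071::svm] object.
#' @slot classes character(3): the pigment class labels.
#' @slot gamma,coef0,cost numeric kernel scale, kernel offset and margin
#'   penalty.
#' @slot scaling numeric `2 x d` matrix of per-feature min (row 1) and max
#'   (row 2) used to map features into `[0, 1]`.
#' @slot encoding `"hsv"` (raw scaled H, S, V) or `"circular"`
#'   (`cos 2*pi*H`, `sin 2*pi*H`, S, V; handles the hue wrap at red).
#' @slot training list with `pixels` (n x 3 RGB matrix) and `labels`
#'   (character vector), the raw training data.
#' @slot formatVersion character, serialization format version.
#'
#' @seealso [trainPigmentClassifier()], [classifyIrisPixels()],
#'   [writePigmentClassifier()]
#' @exportClass PigmentClassifier
setClass("PigmentClassifier",
  representation(model = "ANY", classes = "character", gamma = "numeric",
                 coef0 = "numeric", cost = "numeric", scaling = "matrix",
                 encoding = "character", training = "list",
                 formatVersion = "character"))

setValidity("PigmentClassifier", function(object) {
  if (length(object@classes) != 3L) return("exactly 3 classes required")
  if (nrow(object@scaling) != 2L) return("scaling must be a 2 x d matrix")
  if (!object@encoding %in% c("hsv", "circular"))
    return("encoding must be 'hsv' or 'circular'")
  TRUE
})

.PIGMENT_CLASSES <- c("non_pigmented", "pheomelanin", "eumelanin")
.CLASSIFIER_FORMAT_VERSION <- "1.0"
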