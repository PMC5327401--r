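# Pixel-level pigment classification and the colour quantifiers.
#
# The central phenotype is the triple of areal proportions (non-pigmented,
# pheomelanin, eumelanin) over the segmented iris; the legacy quantifiers
# (mean H/S, melanin index + colour score, Lab means, PIE score, T-index)
# are computed on the same masked pixel set. Each legacy formula is an
# interpretation of the cited prior method, oriented so that melanin-type
# measures rise with increasing eumelanin.

.encodeFeatures <- function(hsv, encoding) {
  if (encoding == "circular") {
    cbind(cos(2 * pi * hsv[, 1L]), sin(2 * pi * hsv[, 1L]),
          hsv[, 2L], hsv[, 3L])
  } else {
    hsv
  }
}

.scaleFeatures <- function(feats, scaling) {
  rng <- scaling[2L, ] - scaling[1L, ]
  rng[rng == 0] <- 1
  sweep(sweep(feats, 2L, scaling[1L, ], "-"), 2L, rng, "/")
}

#' Train the 3-class pigment pixel classifier
#'
#' Fits a one-vs-one soft-margin SVM with quadratic kernel
#' `K(x, y) = (gamma * x.y + coef0)^2` on min-max-scaled HSV features of
#' labelled pixels. Multiclass decisions use the usual one-vs-one majority
#' vote. The raw training pixels are retained in the returned object so
#' that the model serializes to plain JSON and refits identically.
#'
#' @param pixels `n x 3` matrix of labelled RGB pixels (channels in
#'   `[0, 255]`).
#' @param labels character vector over `"non_pigmented"`, `"pheomelanin"`,
#'   `"eumelanin"`, aligned with `pixels`.
#' @param gamma,coef0 quadratic kernel scale and offset (defaults 1, 1).
#' @param cost soft-margin penalty (default 1).
#' @param encoding `"hsv"` (default, raw scaled H/S/V) or `"circular"`
#'   (`cos 2*pi*H, sin 2*pi*H, S, V`), which removes the hue discontinuity
#'   at red.
#' @param minPerClass minimum labelled pixels required per class
#'   (default 20).
#' @return A [PigmentClassifier-class].
#' @examples
#' tr <- syntheticTrainingPixels(nPerClass = 50, seed = 1)
#' model <- trainPigmentClassifier(tr$pixels, tr$labels)
#' model
#' @export
trainPigmentClassifier <- function(pixels, labels, gamma = 1, coef0 = 1,
                                   cost = 1,
                                   encoding = c("hsv", "circular"),
                                   minPerClass = 20L) {
  encoding <- match.arg(encoding)
  pixels <- .assertRgb(pixels)
  labels <- as.character(labels)
  if (length(labels) != nrow(pixels))
    stop("pixels and labels must have equal length", call. = FALSE)
  bad <- setdiff(unique(labels), .PIGMENT_CLASSES)
  if (length(bad))
    stop("unknown pigment class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(labels, levels = .PIGMENT_CLASSES))
  if (any(counts < minPerClass))
    stop(sprintf(
      "class '%s' has %d labelled pixels; at least %d required per class",
      names(counts)[which.min(counts)], min(counts), minPerClass),
      call. = FALSE)
  feats <- .encodeFeatures(rgbToHsv(pixels), encoding)
  scaling <- rbind(apply(feats, 2L, min), apply(feats, 2L, max))
  sc <- .scaleFeatures(feats, scaling)
  dup <- duplicated(sc) | duplicated(sc, fromLast = TRUE)
  if (any(dup) &&
      any(vapply(split(labels[dup], apply(sc[dup, , drop = FALSE], 1L,
                                          paste, collapse = ",")),
                 function(l) length(unique(l)) > 1L, logical(1L))))
    warning("identical features occur in different classes; ",
            "classes are not separable", call. = FALSE)
  fit <- e1071::svm(x = sc, y = factor(labels, levels = .PIGMENT_CLASSES),
                    kernel = "polynomial", degree = 2, gamma = gamma,
                    coef0 = coef0, cost = cost, scale = FALSE)
  new("PigmentClassifier", model = fit, classes = .PIGMENT_CLASSES,
      gamma = gamma, coef0 = coef0, cost = cost, scaling = scaling,
      encoding = encoding,
      training = list(pixels = round(pixels), labels = labels),
      formatVersion = .CLASSIFIER_FORMAT_VERSION)
}

#' Classify iris pixels into pigment classes
#'
#' Converts each RGB pixel to HSV, applies the classifier's stored feature
#' encoding and min-max scaling, and assigns exactly one of the three
#' pigment classes. Deterministic given the model.
#'
#' @param model a [PigmentClassifier-class].
#' @param pixels non-empty `n x 3` RGB matrix (e.g. from [applyMask()]).
#' @return Character vector of class labels, one per pixel.
#' @export
classifyIrisPixels <- function(model, pixels) {
  stopifnot(is(model, "PigmentClassifier"))
  pixels <- .assertRgb(pixels)
  if (nrow(pixels) == 0L)
    stop("empty pixel set: nothing to classify", call. = FALSE)
  feats <- .scaleFeatures(.encodeFeatures(rgbToHsv(pixels), model@encoding),
                          model@scaling)
  as.character(stats::predict(model@model, feats))
}

#' Areal pigment proportions
#'
#' Class counts divided by the total pixel count; the three proportions
#' sum to one.
#'
#' @param labels non-empty character vector of pigment class labels.
#' @return Named numeric(3): `p_non`, `p_pheo`, `p_eu`.
#' @export
pigmentProportions <- function(labels) {
  if (length(labels) == 0L)
    stop("empty label sequence", call. = FALSE)
  counts <- table(factor(labels, levels = .PIGMENT_CLASSES))
  p <- as.numeric(counts) / length(labels)
  names(p) <- c("p_non", "p_pheo", "p_eu")
  p
}

#' Mean hue and saturation of an iris
#'
#' Mean saturation is the arithmetic mean of S. Mean hue is circular by
#' default (hue wraps at red): the angle of the mean unit vector, mapped
#' back into `[0, 1)`; an arithmetic mean is available for comparison.
#'
#' @param pixels non-empty `n x 3` RGB matrix.
#' @param hueMode `"circular"` (default) or `"arithmetic"`.
#' @return Named numeric(2): `mean_h`, `mean_s`.
#' @export
meanHueSaturation <- function(pixels, hueMode = c("circular", "arithmetic")) {
  hueMode <- match.arg(hueMode)
  pixels <- .assertRgb(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  hsv <- rgbToHsv(pixels)
  if (hueMode == "circular") {
    a <- 2 * pi * hsv[, 1L]
    ms <- mean(sin(a)); mc <- mean(cos(a))
    mh <- if (sqrt(ms^2 + mc^2) < 1e-12) 0 else (atan2(ms, mc) / (2 * pi)) %% 1
  } else {
    mh <- mean(hsv[, 1L])
  }
  c(mean_h = mh, mean_s = mean(hsv[, 2L]))
}

#' Melanin index and colour score
#'
#' `lum_l` is one minus the mean relative luminance, oriented as a melanin
#' index (larger = darker = more melanin). `colour_c` is the mean CIE
#' chroma `sqrt(a*^2 + b*^2)` over pixels.
#'
#' @param pixels non-empty `n x 3` RGB matrix.
#' @return Named numeric(2): `lum_l`, `colour_c`.
#' @export
luminosityColourScore <- function(pixels) {
  pixels <- .assertRgb(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  lab <- rgbToLab(pixels)
  c(lum_l = 1 - mean(relativeLuminance(pixels)),
    colour_c = mean(sqrt(lab[, 2L]^2 + lab[, 3L]^2)))
}

#' Mean CIE-L*a*b* components of an iris
#'
#' @param pixels non-empty `n x 3` RGB matrix.
#' @return Named numeric(3): `l_star`, `a_star`, `b_star` (per-component
#'   arithmetic means of pixel Lab values).
#' @export
labSummary <- function(pixels) {
  pixels <- .assertRgb(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  m <- colMeans(rgbToLab(pixels))
  names(m) <- c("l_star", "a_star", "b_star")
  m
}

# Run fn with a fixed RNG stream, restoring the caller's RNG state.
.withFixedSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' PIE score: fraction of brown-like pixels
#'
#' Two-means clustering of the pixels in Lab space (fixed internal seed,
#' 10 restarts, deterministic); the cluster with the lower mean L* is
#' "brown" and the score is the brown pixel fraction. The orientation
#' (counting brown, not blue) makes the score rise with eumelanin.
#' Degenerate single-colour inputs score 1 when their mean L* is below
#' mid-scale (50) and 0 otherwise.
#'
#' @param pixels non-empty `n x 3` RGB matrix.
#' @return Scalar in `[0, 1]`.
#' @export
pieScore <- function(pixels) {
  pixels <- .assertRgb(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  lab <- rgbToLab(pixels)
  nu <- nrow(unique(lab))
  if (nu < 2L)
    return(as.numeric(mean(lab[, 1L]) < 50))
  km <- .withFixedSeed(20170227L, function()
    tryCatch(stats::kmeans(lab, centers = 2L, nstart = 10L, iter.max = 100L),
             error = function(e) NULL))
  if (is.null(km))
    return(as.numeric(mean(lab[, 1L]) < 50))
  meanL <- tapply(lab[, 1L], km$cluster, mean)
  brown <- as.integer(names(meanL)[which.min(meanL)])
  mean(km$cluster == brown)
}

#' T-index: normalized blue-green melanin index
#'
#' `T = 1 - (mean(B) + mean(G)) / (2 * 255)`, i.e. one minus the averaged
#' normalized blue and green channels, so the index rises with melanin
#' (0 for a pure white iris, 1 for black).
#'
#' @param pixels non-empty `n x 3` RGB matrix.
#' @return Scalar in `[0, 1]`.
#' @export
tIndex <- function(pixels) {
  pixels <- .assertRgb(pixels)
  if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  1 - (mean(pixels[, 3L]) + mean(pixels[, 2L])) / (2 * 255)
}

#' Full eye-colour quantification of one image
#'
#' Runs segmentation (unless a segmentation is supplied), extracts the
#' masked iris pixels, classifies them, and computes all quantifiers:
#' the three pigment proportions plus mean H/S, melanin index, colour
#' score, Lab means, PIE score and T-index.
#'
#' @param image an [EyeImage-class].
#' @param model a [PigmentClassifier-class].
#' @param config segmentation parameters ([segmentationConfig()]).
#' @param segmentation optional pre-computed (e.g. manually curated)
#'   [IrisSegmentation-class].
#' @param category optional manual eye-colour category label
#'   (`"blue"`, `"intermediate"`, `"brown"`).
#' @param hueMode hue averaging mode, see [meanHueSaturation()].
#' @return One-row `data.frame` with columns `sample_id`, `p_non`,
#'   `p_pheo`, `p_eu`, `mean_h`, `mean_s`, `lum_l`, `colour_c`, `l_star`,
#'   `a_star`, `b_star`, `pie`, `t_index`, `n_pixels`, `curated`,
#'   `category`.
#' @examples
#' eye <- renderSyntheticEye(syntheticEyeSpec(seed = 3))$image
#' model <- defaultPigmentClassifier()
#' quantifyEye(eye, model)
#' @export
quantifyEye <- function(image, model, config = segmentationConfig(),
                        segmentation = NULL, category = NA_character_,
                        hueMode = "circular") {
  stopifnot(is(image, "EyeImage"), is(model, "PigmentClassifier"))
  if (is.null(segmentation)) segmentation <- segmentIris(image, config)
  px <- applyMask(image, segmentation)
  p <- pigmentProportions(classifyIrisPixels(model, px))
  hs <- meanHueSaturation(px, hueMode = hueMode)
  lc <- luminosityColourScore(px)
  lab <- labSummary(px)
  data.frame(sample_id = image@sampleId,
             p_non = p[["p_non"]], p_pheo = p[["p_pheo"]],
             p_eu = p[["p_eu"]],
             mean_h = hs[["mean_h"]], mean_s = hs[["mean_s"]],
             lum_l = lc[["lum_l"]], colour_c = lc[["colour_c"]],
             l_star = lab[["l_star"]], a_star = lab[["a_star"]],
             b_star = lab[["b_star"]],
             pie = pieScore(px), t_index = tIndex(px),
             n_pixels = nrow(px), curated = segmentation@curated,
             category = category, stringsAsFactors = FALSE)
}

#' Serialize / restore a pigment classifier
#'
#' The model is written as a versioned plain-JSON file holding the kernel
#' hyper-parameters, feature encoding and the raw training pixels;
#' [readPigmentClassifier()] refits the SVM from these, which reproduces
#' the decision function exactly (the fit is deterministic).
#'
#' @param model a [PigmentClassifier-class].
#' @param path JSON file path.
#' @return `writePigmentClassifier` returns `path` invisibly;
#'   `readPigmentClassifier` returns the restored
#'   [PigmentClassifier-class].
#' @export
writePigmentClassifier <- function(model, path) {
  stopifnot(is(model, "PigmentClassifier"))
  obj <- list(format_version = model@formatVersion,
              type = "IrisPheno pigment classifier",
              classes = model@classes, gamma = model@gamma,
              coef0 = model@coef0, cost = model@cost,
              encoding = model@encoding,
              training = list(
                pixels = unname(model@training$pixels),
                labels = model@training$labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePigmentClassifier
#' @export
readPigmentClassifier <- function(path) {
  if (!file.exists(path))
    stop(sprintf("classifier file '%s' does not exist", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != .CLASSIFIER_FORMAT_VERSION)
    stop(sprintf("unsupported classifier format version '%s'",
                 obj$format_version %||% "<missing>"), call. = FALSE)
  trainPigmentClassifier(obj$training$pixels, obj$training$labels,
                         gamma = obj$gamma, coef0 = obj$coef0,
                         cost = obj$cost, encoding = obj$encoding,
                         minPerClass = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The classifier shipped with the package
#'
#' Loads the default pigment classifier, trained on synthetic labelled
#' pixels drawn from the package's three reference class colour
#' distributions (see [syntheticTrainingPixels()]). It stands in for a
#' model trained on hand-labelled iris regions, which are study-specific.
#'
#' @return A [PigmentClassifier-class].
#' @export
defaultPigmentClassifier <- function() {
  readPigmentClassifier(system.file("extdata",
                                    "pigment_classifier_synthetic.json",
                                    package = "IrisPheno", mustWork = TRUE))
}

#' Read manually labelled pixel regions
#'
#' Reads a labelled-regions CSV (columns `image_path`, `class`,
#' `row_min`, `row_max`, `col_min`, `col_max`; 0-based inclusive pixel
#' rectangles) and collects the pixels of each rectangle with its class
#' label, for [trainPigmentClassifier()].
#'
#' @param csvPath path to the labelled-regions CSV.
#' @param imagesDir directory against which relative `image_path` values
#'   are resolved (default: the CSV's directory).
#' @return List with `pixels` (`n x 3` RGB matrix), `labels` (character)
#'   and `provenance` (image paths used).
#' @export
readLabeledRegions <- function(csvPath, imagesDir = NULL) {
  tab <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("image_path", "class", "row_min", "row_max",
            "col_min", "col_max")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("labelled-regions CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(imagesDir)) imagesDir <- dirname(csvPath)
  cache <- new.env(parent = emptyenv())
  pixels <- NULL; labels <- character(0)
  for (i in seq_len(nrow(tab))) {
    p <- tab$image_path[i]
    if (!file.exists(p)) p <- file.path(imagesDir, tab$image_path[i])
    if (is.null(cache[[p]])) cache[[p]] <- readEyeImage(p)
    img <- cache[[p]]@pixels
    rows <- (tab$row_min[i]:tab$row_max[i]) + 1L
    cols <- (tab$col_min[i]:tab$col_max[i]) + 1L
    block <- img[rows, cols, , drop = FALSE]
    pixels <- rbind(pixels, .asPixelMatrix(block))
    labels <- c(labels, rep(tab$class[i], length(rows) * length(cols)))
  }
  list(pixels = pixels, labels = labels,
       provenance = unique(tab$image_path))
}
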