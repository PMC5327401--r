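# Image I/O and colour-space conversions. All pixel-level operations take
# and return n x 3 matrices so that vectorised calls are exactly the map of
# the scalar call.

.assertRgb <- function(rgb) {
  rgb <- .asPixelMatrix(rgb)
  if (nrow(rgb) > 0 && (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255))
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  rgb
}

# Accept a length-3 vector, an n x 3 matrix, or an H x W x 3 array; always
# return an n x 3 matrix (column-major pixel order for arrays).
.asPixelMatrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) stop("an RGB triplet has 3 channels", call. = FALSE)
    matrix(as.numeric(rgb), 1L, 3L)
  } else if (length(dim(rgb)) == 3L) {
    d <- dim(rgb)
    if (d[3L] != 3L) stop("pixel array must have 3 channels", call. = FALSE)
    matrix(as.numeric(rgb), d[1L] * d[2L], 3L)
  } else {
    if (ncol(rgb) != 3L) stop("pixel matrix must have 3 columns", call. = FALSE)
    storage.mode(rgb) <- "double"
    rgb
  }
}

#' Construct an EyeImage
#'
#' @param pixels `H x W x 3` numeric array with channel values in
#'   `[0, 255]` (rounded to integers).
#' @param sampleId sample identifier.
#' @param source provenance string; a file path or `"synthetic"`.
#' @return An [EyeImage-class] object.
#' @export
EyeImage <- function(pixels, sampleId = "eye", source = "memory") {
  storage.mode(pixels) <- "integer"
  new("EyeImage", pixels = pixels, sampleId = as.character(sampleId),
      source = as.character(source))
}

#' Read an eye photograph from disk
#'
#' Decodes an 8-bit RGB image (PNG, JPEG or TIFF). Greyscale images are
#' promoted to RGB by channel replication; an alpha channel, if present,
#' is dropped. Images smaller than 64 x 64 are rejected.
#'
#' @param path path to the image file.
#' @param sampleId sample identifier; defaults to the file stem.
#' @return An [EyeImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' eye <- renderSyntheticEye(syntheticEyeSpec(seed = 1))$image
#' writeEyeImage(eye, f)
#' img <- readEyeImage(f)
#' imageDim(img)
#' @export
readEyeImage <- function(path, sampleId = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("failed to decode image '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  dat <- EBImage::imageData(img)     # x = columns, y = rows, [channels]
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  } else if (dim(dat)[3L] > 3L) {
    dat <- dat[, , 1:3, drop = FALSE]
  } else if (dim(dat)[3L] < 3L) {
    dat <- array(rep(dat[, , 1L], 3L), dim = c(dim(dat)[1:2], 3L))
  }
  # EBImage stores (x, y); transpose to (row, col)
  px <- aperm(dat, c(2L, 1L, 3L))
  px <- round(px * 255)
  if (is.null(sampleId))
    sampleId <- tools::file_path_sans_ext(basename(path))
  EyeImage(px, sampleId = sampleId, source = path)
}

#' Write an EyeImage (or a segmentation overlay) as PNG
#'
#' @param image an [EyeImage-class].
#' @param path output file path (PNG).
#' @param segmentation optional [IrisSegmentation-class]; when supplied the
#'   detected limbus and pupil circles are drawn as green/red overlays for
#'   visual inspection of the segmentation.
#' @return `path`, invisibly.
#' @export
writeEyeImage <- function(image, path, segmentation = NULL) {
  px <- image@pixels / 255
  if (!is.null(segmentation)) {
    for (k in 1:2) {
      circ <- if (k == 1L) segmentation@limbus else segmentation@pupil
      col <- if (k == 1L) c(0, 1, 0) else c(1, 0, 0)
      th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * circ@radius) * 2L)
      rr <- round(circ@centerRow + circ@radius * sin(th)) + 1L
      cc <- round(circ@centerCol + circ@radius * cos(th)) + 1L
      keep <- rr >= 1L & rr <= dim(px)[1L] & cc >= 1L & cc <= dim(px)[2L]
      for (ch in 1:3)
        px[cbind(rr[keep], cc[keep], ch)] <- col[ch]
    }
  }
  EBImage::writeImage(EBImage::Image(aperm(px, c(2L, 1L, 3L)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' RGB to HSV conversion
#'
#' Standard hexcone transform. Hue is returned as a fraction of the full
#' circle in `[0, 1)`; the hue of an achromatic pixel (R = G = B) is
#' defined as 0.
#'
#' @param rgb an RGB triplet, an `n x 3` matrix of triplets, or an
#'   `H x W x 3` array; channels in `[0, 255]`.
#' @return `n x 3` numeric matrix with columns `h`, `s`, `v`, all in
#'   `[0, 1]` (`h < 1`).
#' @examples
#' rgbToHsv(c(255, 0, 0))   # pure red: h = 0, s = 1, v = 1
#' @export
rgbToHsv <- function(rgb) {
  rgb <- .assertRgb(rgb)
  out <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  out[out[, 1L] >= 1, 1L] <- 0
  colnames(out) <- c("h", "s", "v")
  out
}

#' HSV to RGB conversion (inverse of [rgbToHsv()])
#'
#' @param hsv `n x 3` matrix (or length-3 vector) with h in `[0, 1)`,
#'   s and v in `[0, 1]`.
#' @return `n x 3` matrix of RGB channels in `[0, 255]`.
#' @export
hsvToRgb <- function(hsv) {
  if (is.null(dim(hsv))) hsv <- matrix(hsv, 1L, 3L)
  hex <- grDevices::hsv(hsv[, 1L], hsv[, 2L], hsv[, 3L])
  out <- t(grDevices::col2rgb(hex))
  colnames(out) <- c("r", "g", "b")
  out
}

#' RGB to CIE-L*a*b* conversion
#'
#' Standard sRGB -> XYZ -> CIELAB conversion under the D65 white point
#' (the universal default for consumer and clinical imagery; the camera
#' colour profile is not modelled).
#'
#' @inheritParams rgbToHsv
#' @return `n x 3` matrix with columns `l_star` (lightness, `[0, 100]`),
#'   `a_star` (red-green axis) and `b_star` (yellow-blue axis).
#' @examples
#' rgbToLab(c(255, 255, 255))  # white point: L* = 100, a* = b* = 0
#' @export
rgbToLab <- function(rgb) {
  rgb <- .assertRgb(rgb)
  out <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  colnames(out) <- c("l_star", "a_star", "b_star")
  out
}

#' Relative luminance of RGB pixels
#'
#' Rec. 601 luma weights: `(0.299 R + 0.587 G + 0.114 B) / 255`.
#'
#' @inheritParams rgbToHsv
#' @return numeric vector of luminances in `[0, 1]`.
#' @export
relativeLuminance <- function(rgb) {
  rgb <- .assertRgb(rgb)
  as.vector(rgb %*% c(0.299, 0.587, 0.114)) / 255
}

# Greyscale luminance image (H x W matrix in [0,1]) of an EyeImage.
.luminanceImage <- function(image) {
  d <- dim(image@pixels)
  matrix(relativeLuminance(image@pixels), d[1L], d[2L])
}
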