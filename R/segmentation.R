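# Iris segmentation: Canny edges, centre-constrained circular Hough
# transform, and annulus mask construction.
#
# Matrix convolutions are expressed as banded-matrix products (K_rows %*%
# M %*% K_cols), which is fast at the image sizes used here and keeps the
# whole pipeline dependency-light and bit-deterministic.

# Banded smoothing matrix applying a 1-D Gaussian along one dimension,
# rows renormalised so borders do not darken.
.gaussBand <- function(n, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (k in -rad:rad) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- g[k + rad + 1L]
  }
  K / rowSums(K)
}

# Banded derivative (central difference) / triangular smoothing matrices
# for the Sobel operator.
.diffBand <- function(n) {
  K <- matrix(0, n, n)
  i <- 2:(n - 1L)
  K[cbind(i, i - 1L)] <- -1
  K[cbind(i, i + 1L)] <- 1
  K
}
.sobelSmoothBand <- function(n) {
  K <- matrix(0, n, n)
  i <- seq_len(n)
  K[cbind(i, i)] <- 2
  K[cbind(i[-1L], i[-n] )] <- 1
  K[cbind(i[-n], i[-1L])] <- 1
  K / 4
}

.gaussianBlur <- function(M, sigma) {
  .gaussBand(nrow(M), sigma) %*% M %*% t(.gaussBand(ncol(M), sigma))
}

# Shift a matrix by (dr, dc), zero-padding.
.shiftMat <- function(M, dr, dc) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(0, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  out[rs, cs] <- M[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Canny edge detection on the luminance image
#'
#' Runs the Canny pipeline on the relative-luminance greyscale of an eye
#' image: Gaussian smoothing at `sigma`, Sobel gradients, non-maximum
#' suppression along the gradient direction, and hysteresis thresholding
#' with the low/high thresholds placed at the `lowQ`/`highQ` quantiles of
#' the positive gradient magnitudes. A constant image yields an empty edge
#' map (not an error).
#'
#' @param image an [EyeImage-class].
#' @param sigma Gaussian smoothing scale in pixels (default 2).
#' @param lowQ,highQ hysteresis threshold quantiles, `0 < lowQ < highQ < 1`
#'   (defaults 0.70 and 0.90).
#' @return An [EdgeMap-class].
#' @export
detectEdges <- function(image, sigma = 2, lowQ = 0.70, highQ = 0.90) {
  stopifnot(is(image, "EyeImage"))
  if (!(sigma > 0)) stop("sigma must be positive", call. = FALSE)
  if (!(lowQ > 0 && lowQ < highQ && highQ < 1))
    stop("need 0 < lowQ < highQ < 1", call. = FALSE)
  L <- .gaussianBlur(.luminanceImage(image), sigma)
  H <- nrow(L); W <- ncol(L)
  gy <- .diffBand(H) %*% L %*% t(.sobelSmoothBand(W))   # derivative down rows
  gx <- .sobelSmoothBand(H) %*% L %*% t(.diffBand(W))   # derivative across cols
  mag <- sqrt(gx^2 + gy^2)
  mag[mag < 1e-9] <- 0   # numerical dust on flat regions is not gradient
  if (max(mag) == 0)
    return(new("EdgeMap", edges = matrix(FALSE, H, W),
               gradientMagnitude = mag))
  # Non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantised to 4 sectors.
  theta <- atan2(gy, gx)
  sector <- (round(theta / (pi / 4)) %% 4L)
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L),
               `2` = c(1L, 0L), `3` = c(1L, -1L))
  nms <- matrix(FALSE, H, W)
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    keep <- sector == s & mag >= .shiftMat(mag, o[1L], o[2L]) &
            mag >= .shiftMat(mag, -o[1L], -o[2L]) & mag > 0
    nms <- nms | keep
  }
  thr <- stats::quantile(mag[mag > 0], c(lowQ, highQ), names = FALSE)
  strong <- nms & mag >= thr[2L]
  weak <- nms & mag >= thr[1L]
  if (!any(strong))
    return(new("EdgeMap", edges = matrix(FALSE, H, W),
               gradientMagnitude = mag))
  # Hysteresis: keep weak components (8-connected) that contain a strong px.
  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  lab <- t(EBImage::imageData(lab))
  keepLabs <- unique(lab[strong])
  edges <- weak & lab %in% setdiff(keepLabs, 0)
  new("EdgeMap", edges = edges, gradientMagnitude = mag)
}

#' Circular Hough transform with a centre constraint
#'
#' Accumulates votes over integer radii in `[rMin, rMax]` for candidate
#' centres within `centerTolerance` pixels of a reference centre (the image
#' centre by default, mirroring imagery in which the pupil is centred in
#' the middle of the frame). Candidates are ranked by descending
#' accumulator score; at equal score the larger radius wins, which prefers
#' the limbus over internal texture rings.
#'
#' @param edgeMap an [EdgeMap-class].
#' @param rMin,rMax radius search band in pixels,
#'   `0 < rMin < rMax < min(H, W) / 2`.
#' @param centerRow,centerCol reference centre (0-based pixels); defaults
#'   to the image centre.
#' @param centerTolerance maximum distance (pixels) of a candidate centre
#'   from the reference centre.
#' @param maxCandidates maximum number of circles returned.
#' @return A list of [Circle-class] objects sorted by descending score;
#'   empty when no edge pixel supports any candidate.
#' @export
findCircles <- function(edgeMap, rMin, rMax, centerRow = NULL,
                        centerCol = NULL, centerTolerance = 5,
                        maxCandidates = 5L) {
  stopifnot(is(edgeMap, "EdgeMap"))
  H <- nrow(edgeMap@edges); W <- ncol(edgeMap@edges)
  rMin <- as.integer(round(rMin)); rMax <- as.integer(round(rMax))
  if (!(rMin > 0 && rMin < rMax && rMax < min(H, W) / 2 + 1))
    stop("need 0 < rMin < rMax < min(H, W)/2", call. = FALSE)
  if (is.null(centerRow)) centerRow <- (H - 1) / 2
  if (is.null(centerCol)) centerCol <- (W - 1) / 2
  w <- which(edgeMap@edges, arr.ind = TRUE)
  if (nrow(w) == 0L) return(list())
  er <- w[, 1L] - 1; ec <- w[, 2L] - 1
  # integer candidate centres within the tolerance disc
  tol <- max(centerTolerance, 0)
  g <- ceiling(tol)
  cand <- expand.grid(r0 = round(centerRow) + (-g:g),
                      c0 = round(centerCol) + (-g:g))
  keep <- (cand$r0 - centerRow)^2 + (cand$c0 - centerCol)^2 <= max(tol^2, 0.5)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    cand <- data.frame(r0 = round(centerRow), c0 = round(centerCol))
  nbin <- rMax - rMin + 1L
  acc <- matrix(0L, nrow(cand), nbin)
  for (i in seq_len(nrow(cand))) {
    ri <- as.integer(round(sqrt((er - cand$r0[i])^2 + (ec - cand$c0[i])^2)))
    ri <- ri[ri >= rMin & ri <= rMax]
    if (length(ri)) acc[i, ] <- tabulate(ri - rMin + 1L, nbin)
  }
  hit <- which(acc > 0, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(list())
  score <- acc[hit]
  radius <- rMin + hit[, 2L] - 1L
  ord <- order(-score, -radius)
  out <- list()
  selR <- numeric(0); selC <- numeric(0); selRad <- numeric(0)
  for (k in ord) {
    r0 <- cand$r0[hit[k, 1L]]; c0 <- cand$c0[hit[k, 1L]]
    dup <- length(selR) > 0 &&
      any(abs(selR - r0) <= 2 & abs(selC - c0) <= 2 &
          abs(selRad - radius[k]) <= 2)
    if (dup) next
    out[[length(out) + 1L]] <- new("Circle", centerRow = as.numeric(r0),
                                   centerCol = as.numeric(c0),
                                   radius = as.numeric(radius[k]),
                                   score = as.numeric(score[k]))
    selR <- c(selR, r0); selC <- c(selC, c0); selRad <- c(selRad, radius[k])
    if (length(out) >= maxCandidates) break
  }
  out
}

#' Segmentation parameters
#'
#' Defaults: Canny at `sigma = 2` px with hysteresis quantiles 0.70/0.90;
#' limbus radius band 0.20-0.48 of `min(H, W)`; pupil radius band from
#' 0.05 of `min(H, W)` up to 0.60 of the limbus radius; candidate centres
#' within 0.05 of `min(H, W)` of the image centre ("centred in the middle");
#' concentric fallback pupil at 0.30 of the limbus radius when no pupil rim
#' is detected, accepted pupil circles must collect votes on at least
#' `minPupilScoreFrac` of their circumference.
#'
#' @param sigma,lowQ,highQ Canny parameters, see [detectEdges()].
#' @param limbusBand numeric(2), limbus radius band as fractions of
#'   `min(H, W)`.
#' @param pupilBand numeric(2): minimum pupil radius as a fraction of
#'   `min(H, W)` and maximum pupil radius as a fraction of the limbus
#'   radius.
#' @param centerTolerance centre constraint as a fraction of `min(H, W)`.
#' @param fallbackFrac concentric fallback pupil radius as a fraction of
#'   the limbus radius.
#' @param minPupilScoreFrac minimum fraction of the pupil circumference
#'   that must vote for the detected circle to be accepted.
#' @return A named list of parameters for [segmentIris()].
#' @export
segmentationConfig <- function(sigma = 2, lowQ = 0.70, highQ = 0.90,
                               limbusBand = c(0.20, 0.48),
                               pupilBand = c(0.05, 0.60),
                               centerTolerance = 0.05,
                               fallbackFrac = 0.30,
                               minPupilScoreFrac = 0.25) {
  list(sigma = sigma, lowQ = lowQ, highQ = highQ, limbusBand = limbusBand,
       pupilBand = pupilBand, centerTolerance = centerTolerance,
       fallbackFrac = fallbackFrac, minPupilScoreFrac = minPupilScoreFrac)
}

.maskFromCircles <- function(dimHW, limbusCircle, pupilRadius) {
  rr <- matrix(seq_len(dimHW[1L]) - 1, dimHW[1L], dimHW[2L])
  cc <- matrix(seq_len(dimHW[2L]) - 1, dimHW[1L], dimHW[2L], byrow = TRUE)
  d <- sqrt((rr - limbusCircle@centerRow)^2 + (cc - limbusCircle@centerCol)^2)
  d > pupilRadius & d <= limbusCircle@radius
}

.segmentationFailure <- function(sampleId, reason) {
  structure(
    class = c("segmentationFailure", "error", "condition"),
    list(message = sprintf("iris segmentation failed for sample '%s': %s",
                           sampleId, reason),
         call = NULL, sampleId = sampleId, reason = reason))
}

#' Segment the iris annulus in an eye image
#'
#' Two-pass procedure: the limbus is the highest-scoring centre-constrained
#' Hough circle in the outer radius band; the pupil is then searched in an
#' inner band around the limbus centre. When no convincing pupil rim is
#' found (low contrast), a concentric fallback pupil of radius
#' `fallbackFrac * limbus radius` is used, because the colour proportions
#' must be computed relative to the iris annulus, never including the
#' pupil disc.
#'
#' @param image an [EyeImage-class].
#' @param config parameter list from [segmentationConfig()].
#' @return An [IrisSegmentation-class] with `curated = FALSE`.
#'
#' If no limbus candidate survives the centre constraint a condition of
#' class `"segmentationFailure"` carrying the `sampleId` is signalled;
#' such samples can be fixed by [overrideSegmentation()] (the manual
#' curation path).
#' @examples
#' eye <- renderSyntheticEye(syntheticEyeSpec(seed = 7))$image
#' seg <- segmentIris(eye)
#' seg
#' @export
segmentIris <- function(image, config = segmentationConfig()) {
  stopifnot(is(image, "EyeImage"))
  d <- imageDim(image)
  m <- min(d)
  edges <- detectEdges(image, sigma = config$sigma, lowQ = config$lowQ,
                       highQ = config$highQ)
  tol <- config$centerTolerance * m
  limb <- findCircles(edges, rMin = config$limbusBand[1L] * m,
                      rMax = config$limbusBand[2L] * m,
                      centerTolerance = tol)
  if (length(limb) == 0L)
    stop(.segmentationFailure(image@sampleId,
                              "no limbus circle near the image centre"))
  limbusCircle <- limb[[1L]]
  pupRMin <- max(2, round(config$pupilBand[1L] * m))
  pupRMax <- floor(config$pupilBand[2L] * limbusCircle@radius)
  pupilCircle <- NULL
  if (pupRMax > pupRMin) {
    pup <- findCircles(edges, rMin = pupRMin, rMax = pupRMax,
                       centerRow = limbusCircle@centerRow,
                       centerCol = limbusCircle@centerCol,
                       centerTolerance = tol)
    if (length(pup) > 0L) {
      best <- pup[[1L]]
      if (best@score >= config$minPupilScoreFrac * 2 * pi * best@radius)
        pupilCircle <- best
    }
  }
  if (is.null(pupilCircle))
    pupilCircle <- new("Circle", centerRow = limbusCircle@centerRow,
                       centerCol = limbusCircle@centerCol,
                       radius = config$fallbackFrac * limbusCircle@radius,
                       score = 0)
  mask <- .maskFromCircles(d, limbusCircle, pupilCircle@radius)
  new("IrisSegmentation", limbus = limbusCircle, pupil = pupilCircle,
      mask = mask, curated = FALSE)
}

#' Extract the masked iris pixels
#'
#' Returns exactly the pixels where the segmentation mask is `TRUE`, in
#' row-major order (row by row, left to right).
#'
#' @param image an [EyeImage-class].
#' @param segmentation an [IrisSegmentation-class] belonging to `image`.
#' @return `n x 3` numeric matrix of RGB triplets, `n` = mask count.
#' @export
applyMask <- function(image, segmentation) {
  stopifnot(is(image, "EyeImage"), is(segmentation, "IrisSegmentation"))
  d <- imageDim(image)
  if (!identical(dim(segmentation@mask), as.integer(d)) &&
      !identical(dim(segmentation@mask), d))
    stop("segmentation does not match the image dimensions", call. = FALSE)
  w <- which(segmentation@mask, arr.ind = TRUE)
  if (nrow(w) == 0L)
    stop("empty mask: segmentation violates the coverage invariant",
         call. = FALSE)
  o <- order(w[, 1L], w[, 2L])
  lin <- (w[o, 2L] - 1L) * d[1L] + w[o, 1L]
  px <- .asPixelMatrix(image@pixels)
  out <- px[lin, , drop = FALSE]
  colnames(out) <- c("r", "g", "b")
  out
}

#' Manually override a segmentation
#'
#' Builds a curated segmentation from manually supplied limbus and pupil
#' circles, replacing an automatic result or recovering from a
#' segmentation failure (the manual-curation path for falsely segmented
#' irides).
#'
#' @param segmentation an [IrisSegmentation-class], a
#'   `segmentationFailure` condition, or `NULL`.
#' @param limbusCircle,pupilCircle [Circle-class] objects; the pupil
#'   radius must be smaller than the limbus radius.
#' @param image the [EyeImage-class] the circles refer to; optional when
#'   `segmentation` is an `IrisSegmentation` (dimensions are reused).
#' @return An [IrisSegmentation-class] with `curated = TRUE`.
#' @export
overrideSegmentation <- function(segmentation, limbusCircle, pupilCircle,
                                 image = NULL) {
  stopifnot(is(limbusCircle, "Circle"), is(pupilCircle, "Circle"))
  if (pupilCircle@radius >= limbusCircle@radius)
    stop("manual pupil radius must be smaller than the limbus radius",
         call. = FALSE)
  d <- if (is(segmentation, "IrisSegmentation")) {
    dim(segmentation@mask)
  } else if (is(image, "EyeImage")) {
    imageDim(image)
  } else {
    stop("an EyeImage is required to rebuild the mask", call. = FALSE)
  }
  mask <- .maskFromCircles(d, limbusCircle, pupilCircle@radius)
  new("IrisSegmentation", limbus = limbusCircle, pupil = pupilCircle,
      mask = mask, curated = TRUE)
}
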