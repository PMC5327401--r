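# Ground-truthed generators: synthetic eye images (sclera + pupil disc +
# iris annulus with patchy three-class pigment texture) and simulated
# genotype-phenotype cohorts with Balding-Nichols population structure.
# All generators are pure functions of (spec, seed).

#' Reference pigment class colour distributions
#'
#' Mean RGB and per-channel spread of the three pigment classes used by
#' the synthetic eye renderer: non-pigmented areas are light, desaturated
#' blue-grey (stromal scattering), pheomelanin-like areas yellow-brown,
#' eumelanin-like areas dark brown. The three distributions are separated
#' in at least one HSV axis, the regime in which pixel classification is
#' well-posed.
#'
#' @return Named list of `list(mean, sd)` RGB descriptors.
#' @export
defaultClassColours <- function() {
  list(non_pigmented = list(mean = c(148, 168, 200), sd = c(12, 12, 12)),
       pheomelanin = list(mean = c(182, 148, 80), sd = c(12, 12, 12)),
       eumelanin = list(mean = c(72, 48, 34), sd = c(10, 10, 10)))
}

#' Specification of a synthetic eye image
#'
#' Describes a rendered eye: image size, limbus/pupil geometry, sclera
#' and pupil colours, the per-class colour distributions, the requested
#' pigment proportions, the spatial texture scale of the pigment patches,
#' additive channel noise, and the seed.
#'
#' @param height,width image size in pixels (default 128 x 128).
#' @param centerRow,centerCol limbus centre (0-based pixels; default the
#'   image centre).
#' @param limbusRadius,pupilRadius circle radii in pixels (defaults 0.35
#'   and 0.12 of `min(height, width)`).
#' @param proportions numeric(3) `(p_non, p_pheo, p_eu)` summing to 1.
#' @param scleraColour,pupilColour RGB triplets.
#' @param classColours per-class colour distributions
#'   ([defaultClassColours()]).
#' @param textureScale spatial scale (px) of the smoothed-noise pigment
#'   patches (default 6).
#' @param noiseSd additive per-channel Gaussian noise SD (default 4).
#' @param seed integer seed.
#' @param sampleId sample identifier of the rendered image.
#' @return Named list (the spec) for [renderSyntheticEye()].
#' @export
syntheticEyeSpec <- function(height = 128L, width = 128L,
                             centerRow = NULL, centerCol = NULL,
                             limbusRadius = NULL, pupilRadius = NULL,
                             proportions = c(0.80, 0.15, 0.05),
                             scleraColour = c(238, 232, 226),
                             pupilColour = c(18, 16, 16),
                             classColours = defaultClassColours(),
                             textureScale = 6, noiseSd = 4, seed = 1L,
                             sampleId = "synthetic_eye") {
  m <- min(height, width)
  if (is.null(centerRow)) centerRow <- (height - 1) / 2
  if (is.null(centerCol)) centerCol <- (width - 1) / 2
  if (is.null(limbusRadius)) limbusRadius <- 0.35 * m
  if (is.null(pupilRadius)) pupilRadius <- 0.12 * m
  if (!(pupilRadius < limbusRadius && limbusRadius < m / 2))
    stop("need pupil radius < limbus radius < min(H, W)/2", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0))
    stop("proportions must be non-negative and sum to one", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  list(height = as.integer(height), width = as.integer(width),
       centerRow = centerRow, centerCol = centerCol,
       limbusRadius = limbusRadius, pupilRadius = pupilRadius,
       proportions = proportions, scleraColour = scleraColour,
       pupilColour = pupilColour, classColours = classColours,
       textureScale = textureScale, noiseSd = noiseSd,
       seed = as.integer(seed), sampleId = sampleId)
}

#' Render a synthetic eye image with ground truth
#'
#' Deterministic given the spec's seed. Pixels outside the limbus are
#' sclera; inside the pupil radius, pupil. Iris pixels are assigned a
#' pigment class by rank-thresholding a smoothed Gaussian noise field at
#' cut points matching the requested proportions (giving contiguous
#' pigment patches at `textureScale`), colours are drawn from the class
#' colour distribution, and channel noise is added and clipped to
#' `[0, 255]`.
#'
#' @param spec a [syntheticEyeSpec()].
#' @return List with `image` (an [EyeImage-class]) and `truth`: per-pixel
#'   label grid (`sclera`/`pupil`/pigment classes), the true circles, and
#'   requested plus realised proportions.
#' @export
renderSyntheticEye <- function(spec) {
  H <- spec$height; W <- spec$width
  rr <- matrix(seq_len(H) - 1, H, W)
  cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  d <- sqrt((rr - spec$centerRow)^2 + (cc - spec$centerCol)^2)
  irisIdx <- which(d > spec$pupilRadius & d <= spec$limbusRadius)
  nIris <- length(irisIdx)
  counts <- round(cumsum(spec$proportions) * nIris)
  counts <- c(counts[1L], diff(counts))
  if (nIris == 0L || any(counts < 0) ||
      any(spec$proportions > 0 & counts == 0))
    stop("requested proportions are unreachable at this iris pixel count",
         call. = FALSE)
  .withFixedSeed(spec$seed, function() {
    labels <- matrix("sclera", H, W)
    labels[d <= spec$pupilRadius] <- "pupil"
    field <- .gaussianBlur(matrix(stats::rnorm(H * W), H, W),
                           spec$textureScale)
    ord <- irisIdx[order(field[irisIdx])]
    cls <- rep(.PIGMENT_CLASSES, counts)
    labels[ord] <- cls
    px <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(spec$scleraColour[ch], H, W)
      plane[labels == "pupil"] <- spec$pupilColour[ch]
      for (k in .PIGMENT_CLASSES) {
        sel <- which(labels == k)
        cd <- spec$classColours[[k]]
        plane[sel] <- cd$mean[ch] + stats::rnorm(length(sel), 0, cd$sd[ch])
      }
      plane <- plane + stats::rnorm(H * W, 0, spec$noiseSd)
      px[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    realised <- as.numeric(table(factor(labels[irisIdx],
                                        levels = .PIGMENT_CLASSES))) / nIris
    names(realised) <- c("p_non", "p_pheo", "p_eu")
    list(image = EyeImage(px, sampleId = spec$sampleId,
                          source = "synthetic"),
         truth = list(
           labels = labels,
           limbus = new("Circle", centerRow = spec$centerRow,
                        centerCol = spec$centerCol,
                        radius = spec$limbusRadius, score = 0),
           pupil = new("Circle", centerRow = spec$centerRow,
                       centerCol = spec$centerCol,
                       radius = spec$pupilRadius, score = 0),
           proportions_requested = spec$proportions,
           proportions_realised = realised))
  })
}

#' Labelled training pixels from the reference class distributions
#'
#' Draws labelled RGB pixels directly from the per-class colour
#' distributions, for training and testing the pigment classifier without
#' hand-labelled imagery.
#'
#' @param nPerClass pixels per class (default 150).
#' @param colours class colour distributions ([defaultClassColours()]).
#' @param seed integer seed.
#' @return List with `pixels` (`n x 3` RGB matrix) and `labels`.
#' @export
syntheticTrainingPixels <- function(nPerClass = 150L,
                                    colours = defaultClassColours(),
                                    seed = 1L) {
  .withFixedSeed(seed, function() {
    pixels <- NULL; labels <- character(0)
    for (k in .PIGMENT_CLASSES) {
      cd <- colours[[k]]
      block <- sapply(1:3, function(ch)
        pmin(pmax(round(stats::rnorm(nPerClass, cd$mean[ch], cd$sd[ch])),
                  0), 255))
      pixels <- rbind(pixels, block)
      labels <- c(labels, rep(k, nPerClass))
    }
    colnames(pixels) <- c("r", "g", "b")
    list(pixels = pixels, labels = labels)
  })
}

#' Specification of a simulated genotype-phenotype cohort
#'
#' Describes a cohort with population-structured allele frequencies
#' (Balding-Nichols model), additive SNP effects, optional SNP x SNP
#' product-term effects, covariate effects, and residual noise scaled to
#' hit a target genetic variance fraction.
#'
#' @param nIndividuals cohort size (default 3000, >= 50).
#' @param populations population labels (default 7, mirroring a
#'   multi-centre European study design).
#' @param popWeights sampling weights (default equal).
#' @param snpIds SNP identifiers (default 12).
#' @param ancestralFreq per-SNP ancestral minor-allele frequencies in
#'   (0, 1).
#' @param fst per-SNP Balding-Nichols differentiation (scalar recycled;
#'   0 = no structure).
#' @param phenotypes named list; each element is a list with `betas`
#'   (numeric, per SNP), optional `interactions` (list of
#'   `list(pair = c(id, id), beta3 = x)`), `h2` (target genetic variance
#'   fraction in `[0, 1)`), and optional `ageBeta`, `sexBeta`.
#' @param ageRange sampling range of age in years (default 65-85, an
#'   elderly study population).
#' @param seed integer seed.
#' @return Named list (the spec) for [simulateCohort()].
#' @export
cohortSpec <- function(nIndividuals = 3000L,
                       populations = paste0("pop", 1:7),
                       popWeights = NULL,
                       snpIds = paste0("snp", 1:12),
                       ancestralFreq = seq(0.10, 0.45,
                                           length.out = length(snpIds)),
                       fst = 0.02,
                       phenotypes = list(
                         p_non = list(betas = c(2, rep(0.5, 5),
                                                rep(0.25, 6)),
                                      h2 = 0.5)),
                       ageRange = c(65, 85), seed = 1L) {
  if (nIndividuals < 50L) stop("nIndividuals must be >= 50", call. = FALSE)
  if (any(ancestralFreq <= 0 | ancestralFreq >= 1))
    stop("ancestral frequencies must lie in (0, 1)", call. = FALSE)
  if (is.null(popWeights))
    popWeights <- rep(1 / length(populations), length(populations))
  fst <- rep_len(fst, length(snpIds))
  for (ph in phenotypes) {
    if (length(ph$betas) != length(snpIds))
      stop("each phenotype needs one beta per SNP", call. = FALSE)
    if (!is.null(ph$h2) && (ph$h2 < 0 || ph$h2 >= 1))
      stop("target variance explained must lie in [0, 1)", call. = FALSE)
  }
  list(nIndividuals = as.integer(nIndividuals), populations = populations,
       popWeights = popWeights, snpIds = snpIds,
       ancestralFreq = ancestralFreq, fst = fst, phenotypes = phenotypes,
       ageRange = ageRange, seed = as.integer(seed))
}

#' Simulate a genotype-phenotype cohort
#'
#' Individuals are assigned to populations by the sampling weights;
#' per-population allele frequencies are drawn from the Balding-Nichols
#' beta model around the ancestral frequency (inducing the Wahlund-type
#' pooled-sample HWE deviations seen in structured cohorts); genotypes
#' are `Binomial(2, freq)` within population (HWE by construction). Age
#' is uniform over `ageRange`, sex Bernoulli(0.5). Each phenotype is its
#' genetic linear predictor (main + product terms) plus covariate effects
#' plus Gaussian noise with SD chosen so the genetic variance fraction
#' (relative to genetic + residual variance) matches the target `h2`.
#'
#' @param spec a [cohortSpec()].
#' @return List with `genotypes` (n x m dosage matrix), `covariates`
#'   (`data.frame`: `sample_id`, `age`, `sex`, `population`),
#'   `phenotypes` (`data.frame` keyed by `sample_id`), and `truth`
#'   (generating parameters plus realised variance components).
#' @examples
#' ch <- simulateCohort(cohortSpec(nIndividuals = 200, seed = 2))
#' snpSummary(ch$genotypes, ch$covariates$population)[1:3, ]
#' @export
simulateCohort <- function(spec) {
  .withFixedSeed(spec$seed, function() {
    n <- spec$nIndividuals
    K <- length(spec$populations)
    pop <- sample(spec$populations, n, replace = TRUE,
                  prob = spec$popWeights)
    m <- length(spec$snpIds)
    popFreq <- matrix(NA_real_, K, m,
                      dimnames = list(spec$populations, spec$snpIds))
    G <- matrix(NA_integer_, n, m,
                dimnames = list(sprintf("ind%04d", seq_len(n)),
                                spec$snpIds))
    for (j in seq_len(m)) {
      p <- spec$ancestralFreq[j]; f <- spec$fst[j]
      popFreq[, j] <- if (f > 0)
        stats::rbeta(K, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      else rep(p, K)
      G[, j] <- stats::rbinom(n, 2L, popFreq[match(pop, spec$populations), j])
    }
    age <- stats::runif(n, spec$ageRange[1L], spec$ageRange[2L])
    sex <- stats::rbinom(n, 1L, 0.5)
    cov <- data.frame(sample_id = rownames(G), age = age, sex = sex,
                      population = pop, stringsAsFactors = FALSE)
    phen <- data.frame(sample_id = rownames(G), stringsAsFactors = FALSE)
    truthPh <- list()
    for (phName in names(spec$phenotypes)) {
      ph <- spec$phenotypes[[phName]]
      eta <- as.vector(G %*% ph$betas)
      for (ia in ph$interactions %||% list())
        eta <- eta + ia$beta3 * G[, ia$pair[1L]] * G[, ia$pair[2L]]
      varG <- stats::var(eta)
      h2 <- ph$h2 %||% 0.5
      if (h2 > 0 && varG == 0)
        stop(sprintf(
          "phenotype '%s': non-zero variance target with zero genetic variance",
          phName), call. = FALSE)
      sdE <- if (h2 > 0) sqrt(varG * (1 - h2) / h2) else 1
      y <- eta + (ph$ageBeta %||% 0) * age + (ph$sexBeta %||% 0) * sex +
        stats::rnorm(n, 0, sdE)
      phen[[phName]] <- y
      truthPh[[phName]] <- list(betas = ph$betas,
                                interactions = ph$interactions %||% list(),
                                h2_target = h2, var_genetic = varG,
                                sd_residual = sdE,
                                h2_realised = varG / (varG + sdE^2))
    }
    list(genotypes = G, covariates = cov, phenotypes = phen,
         truth = list(popFreq = popFreq, phenotypes = truthPh,
                      spec = spec))
  })
}

.writeLabelGrid <- function(labels, path) {
  lv <- c("sclera", "pupil", .PIGMENT_CLASSES)
  idx <- matrix(match(labels, lv) - 1L, nrow(labels), ncol(labels))
  EBImage::writeImage(EBImage::Image(t(idx) / 255), path)
  invisible(path)
}

#' Generate a standard fixture set on disk
#'
#' Writes a deterministic suite of synthetic inputs for end-to-end runs:
#' eye images spanning blue-like, intermediate-like and brown-like
#' pigment proportions with varying iris geometry (plus indexed
#' ground-truth label grids), one simulated cohort (genotype, covariate
#' and phenotype CSVs with a JSON truth record), and a manifest CSV with
#' per-file MD5 checksums and ground truth.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed.
#' @param nEyes number of eye images (default 60, split over the three
#'   category archetypes).
#' @param cohortN cohort size (default 3000).
#' @param imageSize eye image side length in pixels (default 128).
#' @return The manifest `data.frame`, invisibly.
#' @export
makeFixtureSuite <- function(outDir, seed = 1L, nEyes = 60L,
                             cohortN = 3000L, imageSize = 128L) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop(sprintf("cannot write to '%s'", outDir), call. = FALSE)
  archetypes <- list(blue = c(0.85, 0.10, 0.05),
                     intermediate = c(0.40, 0.40, 0.20),
                     brown = c(0.10, 0.25, 0.65))
  manifest <- NULL
  cats <- rep(names(archetypes), length.out = nEyes)
  radii <- .withFixedSeed(seed, function()
    stats::runif(nEyes, 0.25, 0.45))
  for (i in seq_len(nEyes)) {
    sid <- sprintf("eye_%03d", i)
    spec <- syntheticEyeSpec(
      height = imageSize, width = imageSize,
      limbusRadius = radii[i] * imageSize,
      pupilRadius = 0.35 * radii[i] * imageSize,
      proportions = archetypes[[cats[i]]],
      seed = seed + i, sampleId = sid)
    r <- renderSyntheticEye(spec)
    imgFile <- file.path(outDir, paste0(sid, ".png"))
    labFile <- file.path(outDir, paste0(sid, "_labels.png"))
    writeEyeImage(r$image, imgFile)
    .writeLabelGrid(r$truth$labels, labFile)
    pr <- r$truth$proportions_realised
    manifest <- rbind(manifest, data.frame(
      file = basename(c(imgFile, labFile)),
      kind = c("eye_image", "label_grid"), sample_id = sid,
      category = cats[i], p_non = pr[["p_non"]], p_pheo = pr[["p_pheo"]],
      p_eu = pr[["p_eu"]], limbus_r = spec$limbusRadius,
      pupil_r = spec$pupilRadius,
      md5 = unname(tools::md5sum(c(imgFile, labFile))),
      stringsAsFactors = FALSE))
  }
  ch <- simulateCohort(cohortSpec(
    nIndividuals = cohortN, seed = seed + 10000L,
    phenotypes = list(
      p_non = list(betas = c(2, rep(0.5, 5), rep(0.25, 6)), h2 = 0.5,
                   interactions = list(
                     list(pair = c("snp1", "snp4"), beta3 = 0.6),
                     list(pair = c("snp2", "snp7"), beta3 = 0.5))))))
  gf <- file.path(outDir, "genotypes.csv")
  cf <- file.path(outDir, "covariates.csv")
  pf <- file.path(outDir, "phenotypes.csv")
  tf <- file.path(outDir, "cohort_truth.json")
  utils::write.csv(data.frame(sample_id = rownames(ch$genotypes),
                              ch$genotypes, check.names = FALSE),
                   gf, row.names = FALSE)
  utils::write.csv(ch$covariates, cf, row.names = FALSE)
  utils::write.csv(ch$phenotypes, pf, row.names = FALSE)
  jsonlite::write_json(ch$truth[c("popFreq", "phenotypes")], tf,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (f in c(gf, cf, pf, tf))
    manifest <- rbind(manifest, data.frame(
      file = basename(f), kind = "cohort", sample_id = NA,
      category = NA, p_non = NA, p_pheo = NA, p_eu = NA, limbus_r = NA,
      pupil_r = NA, md5 = unname(tools::md5sum(f)),
      stringsAsFactors = FALSE))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
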