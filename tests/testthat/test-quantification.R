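test_that("the SVM separates well-separated HSV clusters almost perfectly", {
  tr <- syntheticTrainingPixels(nPerClass = 200, seed = 1)
  model <- trainPigmentClassifier(tr$pixels, tr$labels)
  fresh <- syntheticTrainingPixels(nPerClass = 334, seed = 2)
  acc <- mean(classifyIrisPixels(model, fresh$pixels) == fresh$labels)
  expect_gte(acc, 0.99)
})

test_that("training validates class coverage and labels", {
  tr <- syntheticTrainingPixels(nPerClass = 50, seed = 1)
  one <- tr$labels == "eumelanin"
  expect_error(trainPigmentClassifier(tr$pixels[one, ], tr$labels[one]),
               "at least")
  expect_error(trainPigmentClassifier(tr$pixels,
                                      rep("melanin", nrow(tr$pixels))),
               "unknown pigment class")
  expect_warning(
    trainPigmentClassifier(constPixels(c(100, 100, 100), 60),
                           rep(c("non_pigmented", "pheomelanin",
                                 "eumelanin"), each = 20),
                           minPerClass = 20L),
    "not separable")
})

test_that("reference class distributions are separated in at least one HSV axis", {
  tr <- syntheticTrainingPixels(nPerClass = 300, seed = 7)
  hsv <- rgbToHsv(tr$pixels)
  cls <- unique(tr$labels)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- hsv[tr$labels == cls[i], , drop = FALSE]
    b <- hsv[tr$labels == cls[j], , drop = FALSE]
    disjoint <- vapply(1:3, function(k)
      min(a[, k]) > max(b[, k]) || min(b[, k]) > max(a[, k]), logical(1))
    expect_true(any(disjoint),
                label = sprintf("classes %s/%s disjoint in some axis",
                                cls[i], cls[j]))
  }
})

test_that("classification is deterministic and handles extremes", {
  model <- defaultPigmentClassifier()
  # all-black pixels fall in the darkest (eumelanin) class
  expect_true(all(classifyIrisPixels(model, constPixels(c(0, 0, 0), 50)) ==
                    "eumelanin"))
  # a training pixel deep inside its class keeps its label
  tr <- model@training
  core <- defaultClassColours()$non_pigmented$mean
  expect_identical(classifyIrisPixels(model, matrix(core, 1)),
                   "non_pigmented")
  expect_error(classifyIrisPixels(model, matrix(numeric(0), 0, 3)),
               "empty")
})

test_that("pigment proportions are counts over total and sum to one", {
  expect_equal(pigmentProportions(rep("eumelanin", 10)),
               c(p_non = 0, p_pheo = 0, p_eu = 1))
  expect_equal(pigmentProportions(rep(c("non_pigmented", "pheomelanin",
                                        "eumelanin"), 7)),
               c(p_non = 1 / 3, p_pheo = 1 / 3, p_eu = 1 / 3))
  set.seed(4)
  for (i in 1:5) {
    lab <- sample(c("non_pigmented", "pheomelanin", "eumelanin"),
                  sample(5:200, 1), replace = TRUE)
    expect_equal(sum(pigmentProportions(lab)), 1, tolerance = 1e-12)
  }
  expect_error(pigmentProportions(character(0)), "empty")
})

test_that("mean hue is circular by default and saturation arithmetic", {
  px <- constPixels(c(182, 148, 80), 40)
  hs <- meanHueSaturation(px)
  expect_equal(unname(hs), unname(rgbToHsv(px[1, ])[1, 1:2]),
               tolerance = 1e-12)
  # hues on both sides of the red wrap average to 0 circularly
  wrap <- hsvToRgb(rbind(c(0.97, 1, 1), c(0.03, 1, 1)))
  mh <- meanHueSaturation(wrap)[["mean_h"]]
  expect_lte(min(mh, 1 - mh), 0.005)
  # ... but not arithmetically
  mha <- meanHueSaturation(wrap, hueMode = "arithmetic")[["mean_h"]]
  expect_equal(mha, 0.5, tolerance = 0.01)
  expect_equal(meanHueSaturation(constPixels(c(77, 77, 77)))[["mean_s"]], 0)
})

test_that("melanin index and colour score have the documented limits", {
  expect_equal(unname(luminosityColourScore(constPixels(c(255, 255, 255)))),
               c(0, 0), tolerance = 1e-9)
  expect_equal(unname(luminosityColourScore(constPixels(c(0, 0, 0)))),
               c(1, 0), tolerance = 1e-9)
  rgb <- c(200, 30, 40)
  cc <- luminosityColourScore(constPixels(rgb))[["colour_c"]]
  oracle <- cieLabOracle(rgb)
  expect_equal(cc, sqrt(oracle[2]^2 + oracle[3]^2), tolerance = 0.5)
})

test_that("Lab summaries are per-component means", {
  rgb <- c(120, 90, 60)
  expect_equal(unname(labSummary(constPixels(rgb))),
               unname(rgbToLab(rgb)[1, ]), tolerance = 1e-12)
  a <- c(50, 100, 150); b <- c(210, 40, 90)
  mix <- rbind(constPixels(a, 30), constPixels(b, 30))
  expect_equal(unname(labSummary(mix)),
               unname((rgbToLab(a)[1, ] + rgbToLab(b)[1, ]) / 2),
               tolerance = 1e-9)
  grey <- labSummary(constPixels(c(130, 130, 130)))
  expect_equal(unname(grey[2:3]), c(0, 0), tolerance = 1e-6)
})

test_that("PIE score counts the brown-like cluster fraction", {
  expect_equal(pieScore(constPixels(c(40, 30, 25))), 1)   # uniform dark
  expect_equal(pieScore(constPixels(c(220, 225, 230))), 0) # uniform light
  set.seed(9)
  dark <- constPixels(c(60, 60, 60), 300) +
    matrix(rnorm(900, 0, 3), 300, 3)
  light <- constPixels(c(200, 200, 200), 700) +
    matrix(rnorm(2100, 0, 3), 700, 3)
  px <- pmin(pmax(rbind(dark, light), 0), 255)
  expect_equal(pieScore(px), 0.30, tolerance = 0.02)
})

test_that("T-index is the normalized blue-green melanin index", {
  expect_equal(tIndex(constPixels(c(255, 255, 255))), 0)
  expect_equal(tIndex(constPixels(c(0, 0, 0))), 1)
  expect_equal(tIndex(constPixels(c(100, 51, 204))), 0.5)
})

test_that("quantifyEye recovers planted proportions and is bit-deterministic", {
  model <- defaultPigmentClassifier()
  for (props in list(c(0.9, 0.06, 0.04), c(0.2, 0.3, 0.5))) {
    eye <- renderSyntheticEye(syntheticEyeSpec(proportions = props,
                                               seed = 31))$image
    q <- quantifyEye(eye, model)
    expect_lte(max(abs(c(q$p_non, q$p_pheo, q$p_eu) - props)), 0.05)
    expect_equal(q$p_non + q$p_pheo + q$p_eu, 1, tolerance = 1e-9)
  }
  eye <- renderSyntheticEye(syntheticEyeSpec(seed = 32))$image
  expect_identical(quantifyEye(eye, model), quantifyEye(eye, model))
})

test_that("melanin measures are monotone in the planted eumelanin fraction", {
  model <- defaultPigmentClassifier()
  eus <- c(0.1, 0.3, 0.5, 0.7)
  rows <- do.call(rbind, lapply(eus, function(pe) {
    props <- c((1 - pe) * 0.7, (1 - pe) * 0.3, pe)
    eye <- renderSyntheticEye(syntheticEyeSpec(proportions = props,
                                               seed = 33))$image
    quantifyEye(eye, model)
  }))
  expect_true(all(diff(rows$p_eu) >= 0))
  expect_true(all(diff(rows$lum_l) >= 0))
  expect_true(all(diff(rows$t_index) >= 0))
})

test_that("recovered proportions are robust to the kernel choice", {
  tr <- syntheticTrainingPixels(nPerClass = 200, seed = 5)
  quad <- trainPigmentClassifier(tr$pixels, tr$labels)
  feats <- IrisPheno:::.scaleFeatures(
    IrisPheno:::.encodeFeatures(rgbToHsv(tr$pixels), "hsv"), quad@scaling)
  radial <- e1071::svm(x = feats,
                       y = factor(tr$labels,
                                  levels = quad@classes),
                       kernel = "radial", cost = 1, scale = FALSE)
  eye <- renderSyntheticEye(syntheticEyeSpec(proportions = c(0.5, 0.3, 0.2),
                                             seed = 34))$image
  seg <- segmentIris(eye)
  px <- applyMask(eye, seg)
  pQuad <- pigmentProportions(classifyIrisPixels(quad, px))
  fr <- IrisPheno:::.scaleFeatures(
    IrisPheno:::.encodeFeatures(rgbToHsv(px), "hsv"), quad@scaling)
  pRad <- pigmentProportions(as.character(predict(radial, fr)))
  expect_lt(max(abs(pQuad - pRad)), 0.02)
})

test_that("serialized classifiers round-trip to identical labels", {
  tr <- syntheticTrainingPixels(nPerClass = 60, seed = 8)
  model <- trainPigmentClassifier(tr$pixels, tr$labels)
  f <- tempfile(fileext = ".json")
  writePigmentClassifier(model, f)
  back <- readPigmentClassifier(f)
  probe <- syntheticTrainingPixels(nPerClass = 200, seed = 9)$pixels
  expect_identical(classifyIrisPixels(model, probe),
                   classifyIrisPixels(back, probe))
  expect_identical(back@formatVersion, model@formatVersion)
})
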