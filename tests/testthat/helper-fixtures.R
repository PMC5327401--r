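# Shared fixtures and independent oracles, all built in code.

# Independent CIELAB oracle: direct evaluation of the published CIE
# equations (sRGB EOTF -> linear RGB -> XYZ (D65) -> L*a*b*), kept separate
# from the package's conversion path.
cieLabOracle <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  wp <- as.vector(M %*% c(1, 1, 1))   # D65 white
  t <- xyz / wp
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
}

# A constant-colour EyeImage (>= 64 x 64).
constantImage <- function(rgb, h = 96L, w = 96L, sampleId = "const") {
  px <- array(rep(rgb, each = h * w), dim = c(h, w, 3L))
  EyeImage(px, sampleId = sampleId)
}

# Constant-colour pixel matrix.
constPixels <- function(rgb, n = 100L) {
  matrix(rep(rgb, each = n), n, 3L)
}

# An EdgeMap containing only the rasterised circle(s) given as a list of
# c(centerRow, centerCol, radius); dense angular sampling.
circleEdgeMap <- function(h, w, circles) {
  e <- matrix(FALSE, h, w)
  for (ci in circles) {
    th <- seq(0, 2 * pi, length.out = ceiling(8 * ci[3]))
    rr <- round(ci[1] + ci[3] * sin(th)) + 1L
    cc <- round(ci[2] + ci[3] * cos(th)) + 1L
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    e[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mag <- matrix(0, h, w); mag[e] <- 1
  new("EdgeMap", edges = e, gradientMagnitude = mag)
}

# Small well-separated cohort used across genetics tests.
testCovariates <- function(n, nPop = 3L, seed = 42L) {
  set.seed(seed)
  data.frame(age = runif(n, 65, 85), sex = rbinom(n, 1L, 0.5),
             population = sample(paste0("pop", seq_len(nPop)), n,
                                 replace = TRUE),
             stringsAsFactors = FALSE)
}

# Independent HWE oracle: recurrence-based enumeration (ratio of successive
# heterozygote-count probabilities), a different route than the lgamma
# closed form used by the implementation.
hweOracle <- function(nAA, nAa, naa) {
  N <- nAA + nAa + naa
  nrare <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (nrare == 0) return(1)
  hs <- seq(nrare %% 2, nrare, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  for (k in seq_along(hs)[-1]) {
    h <- hs[k]
    # P(h) / P(h-2) = 4 * homRare(h-2) * homCommon(h-2) / (h * (h-1))
    hr <- (nrare - (h - 2)) / 2
    hc <- N - (h - 2) - hr
    probs[k] <- probs[k - 1] * 4 * hr * hc / (h * (h - 1))
  }
  probs <- probs / sum(probs)
  pObs <- probs[hs == nAa]
  sum(probs[probs <= pObs * (1 + 1e-12)])
}
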