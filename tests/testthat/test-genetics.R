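
test_that("the exact HWE test matches enumeration and its known cases", {
  expect_identical(hweExactTest(20, 0, 0), 1)
  # perfect HWE proportions give the largest attainable p for these
  # allele counts
  pPerfect <- hweExactTest(25, 50, 25)
  hs <- seq(0, 100, by = 2)
  allP <- vapply(hs, function(h)
    hweExactTest((100 - h) / 2, h, 100 - (100 - h) / 2 - h), numeric(1))
  expect_equal(pPerfect, max(allP))
  set.seed(21)
  for (i in 1:200) {
    N <- sample(1:50, 1)
    nAa <- sample(0:N, 1)
    nAA <- sample(0:(N - nAa), 1)
    naa <- N - nAa - nAA
    expect_equal(hweExactTest(nAA, nAa, naa), hweOracle(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
})

test_that("dosage LD r2 behaves for identical, mirrored and independent SNPs", {
  g <- rbinom(500, 2, 0.3)
  expect_equal(ldR2(g, g), 1)
  expect_equal(ldR2(g, 2 - g), 1)
  set.seed(22)
  a <- rbinom(10000, 2, 0.3); b <- rbinom(10000, 2, 0.3)
  expect_lt(ldR2(a, b), 0.01)
  expect_warning(r <- ldR2(rep(1, 10), rbinom(10, 2, 0.5)), "constant")
  expect_true(is.na(r))
})

test_that("ancestry informativeness matches the formula oracle", {
  # identical frequencies across populations carry no information
  set.seed(23)
  g <- rbinom(600, 2, 0.4)
  pop <- rep(c("a", "b", "c"), 200)
  expect_equal(ancestryInformativeness(g, pop), 0, tolerance = 0.02)
  # fixed alternate alleles in two populations: ln 2
  expect_equal(ancestryInformativeness(c(0, 0, 2, 2),
                                       c("a", "a", "b", "b")), log(2))
  # 3-population configuration vs a direct evaluation
  freqs <- c(0.1, 0.5, 0.9)
  g3 <- c(rbinom(400, 2, freqs[1]), rbinom(400, 2, freqs[2]),
          rbinom(400, 2, freqs[3]))
  pop3 <- rep(c("x", "y", "z"), each = 400)
  fHat <- tapply(g3, pop3, mean)[c("x", "y", "z")] / 2
  oracle <- 0
  for (fa in list(fHat, 1 - fHat)) {
    pbar <- mean(fa)
    oracle <- oracle - ifelse(pbar > 0, pbar * log(pbar), 0) +
      sum(ifelse(fa > 0, fa * log(fa), 0)) / 3
  }
  expect_equal(ancestryInformativeness(g3, pop3), oracle,
               tolerance = 1e-12)
  expect_error(ancestryInformativeness(g, rep("a", 600)), "2 populations")
})

test_that("partial-correlation association recovers planted variance", {
  set.seed(24)
  g <- rbinom(200, 2, 0.4)
  a <- snpAssociation(g, g + 0, NULL)
  expect_equal(a$r2, 100, tolerance = 1e-9)
  expect_lt(a$p, 1e-100)
  # null: no association
  cov <- testCovariates(5000)
  g0 <- rbinom(5000, 2, 0.3)
  a0 <- snpAssociation(g0, rnorm(5000), cov)
  expect_lt(a0$r2, 0.2)
  # planted 50% of residual variance at n = 3000
  g1 <- rbinom(3000, 2, 0.3)
  beta <- 1
  sdE <- sqrt(var(g1) * 1)   # equal genetic and residual variance
  y <- beta * g1 + 0.05 * cov$age[1:3000] + rnorm(3000, 0, sdE)
  a1 <- snpAssociation(g1, y, cov[1:3000, ])
  expect_equal(a1$r2, 50, tolerance = 3)
})

test_that("association p-values are uniform under the null", {
  set.seed(25)
  cov <- testCovariates(200)
  ps <- vapply(1:400, function(i)
    snpAssociation(rbinom(200, 2, 0.3), rnorm(200), cov)$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("squared partial correlation equals the regression t relation", {
  set.seed(26)
  for (i in 1:20) {
    n <- 150
    cov <- testCovariates(n, seed = 100 + i)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- runif(1, -1, 1) * g + 0.02 * cov$age + 0.3 * cov$sex + rnorm(n)
    a <- snpAssociation(g, y, cov)
    fit <- lm(y ~ g + age + sex + factor(population), data = cov)
    tg <- summary(fit)$coefficients["g", "t value"]
    df <- fit$df.residual
    expect_equal(a$r2 / 100, tg^2 / (tg^2 + df), tolerance = 1e-10)
    expect_equal(a$beta, unname(coef(fit)["g"]), tolerance = 1e-10)
    expect_equal(a$p,
                 summary(fit)$coefficients["g", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
})

test_that("the combined model is consistent with single-SNP fits", {
  set.seed(27)
  n <- 2000
  cov <- testCovariates(n)
  G <- cbind(s1 = rbinom(n, 2, 0.3))
  y <- 0.7 * G[, 1] + rnorm(n)
  comb <- combinedAssociation(G, y, cov)
  single <- snpAssociation(G[, 1], y, cov, snpId = "s1")
  expect_equal(comb$snps$beta, single$beta, tolerance = 1e-10)
  expect_equal(comb$snps$p, single$p, tolerance = 1e-8)

  # two independent causal SNPs with ~10% planned variance each
  g1 <- rbinom(3000, 2, 0.3); g2 <- rbinom(3000, 2, 0.3)
  vG <- var(g1) + var(g2)
  y2 <- g1 + g2 + rnorm(3000, 0, sqrt(4 * vG))  # each ~10% of total
  comb2 <- combinedAssociation(cbind(a = g1, b = g2), y2)
  expect_equal(comb2$adj_r2, 20, tolerance = 3)

  # duplicated SNP columns are dropped with a warning
  expect_warning(
    comb3 <- combinedAssociation(cbind(a = g1, b = g1), y2),
    "collinear")
  expect_identical(comb3$dropped, "b")
})

test_that("the interaction F-test detects planted epistasis and flags degeneracy", {
  set.seed(28)
  n <- 3000
  cov <- testCovariates(n)
  gA <- rbinom(n, 2, 0.3); gB <- rbinom(n, 2, 0.3)
  y <- 0.5 * gA + 0.4 * gB + 0.3 * gA * gB + rnorm(n)
  it <- interactionTest(gA, gB, y, cov)
  expect_false(it$untestable)
  expect_lt(it$p, 1e-6)
  expect_equal(it$beta3, 0.3, tolerance = 0.15)
  # identical SNPs are untestable
  it2 <- interactionTest(gA, gA, y, cov)
  expect_true(it2$untestable)
  # monomorphic SNP is untestable
  it3 <- interactionTest(gA, rep(0, n), y, cov)
  expect_true(it3$untestable)
})

test_that("the interaction scan excludes high-LD pairs and ranks the true pair first", {
  set.seed(29)
  n <- 2000
  cov <- testCovariates(n)
  G <- sapply(1:4, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:4)
  y1 <- 0.4 * G[, 1] + 0.5 * G[, 1] * G[, 2] + rnorm(n)
  y2 <- rnorm(n)
  scan <- interactionScan(G, data.frame(ph1 = y1, ph2 = y2), cov)
  expect_identical(nrow(scan), 12L)   # 6 pairs x 2 phenotypes
  top <- scan[1, ]
  expect_identical(sort(c(top$snp_a, top$snp_b)), c("s1", "s2"))
  expect_identical(top$phenotype, "ph1")
  expect_true(top$passes_bonferroni)

  # a pair in strong LD is absent from the scan
  G2 <- cbind(G, s5 = ifelse(rbinom(n, 1, 0.01) == 1,
                             2 - G[, 4], G[, 4]))
  expect_gt(suppressWarnings(ldR2(G2[, "s4"], G2[, "s5"])), 0.85)
  scan2 <- interactionScan(G2, data.frame(ph2 = y2), cov,
                           ldThreshold = 0.8)
  expect_false(any(scan2$snp_a == "s4" & scan2$snp_b == "s5"))
  expect_identical(nrow(scan2), 9L)   # 10 pairs - 1 excluded
})

test_that("prediction models recover noiseless coefficients exactly", {
  set.seed(30)
  n <- 400
  G <- cbind(x1 = rbinom(n, 2, 0.4), x2 = rbinom(n, 2, 0.2))
  cov <- testCovariates(n)
  y <- 2 * G[, "x1"] + cov$age
  fit <- fitPredictionModel(predictionModelSpec("y", c("x1", "x2"),
                                                covariates = "age"),
                            G, y, cov)
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["age"]), 1, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 100, tolerance = 1e-8)

  # pure-noise phenotype: adjusted R2 near zero
  G12 <- sapply(1:12, function(i) rbinom(1000, 2, 0.3))
  colnames(G12) <- paste0("s", 1:12)
  fit0 <- fitPredictionModel(
    predictionModelSpec("y", colnames(G12), covariates = character(0)),
    G12, rnorm(1000), NULL)
  expect_lt(abs(fit0$adj_r2), 2)

  # a truly null interaction term barely moves the adjusted R2
  n3 <- 3000
  G3 <- sapply(1:3, function(i) rbinom(n3, 2, 0.3))
  colnames(G3) <- paste0("s", 1:3)
  y3 <- 0.5 * G3[, 1] + 0.5 * G3[, 2] + rnorm(n3)
  f1 <- fitPredictionModel(predictionModelSpec("y", colnames(G3),
                                               covariates = character(0)),
                           G3, y3, NULL)
  f2 <- fitPredictionModel(
    predictionModelSpec("y", colnames(G3),
                        interactions = list(c("s1", "s2")),
                        covariates = character(0)),
    G3, y3, NULL)
  expect_lt(abs(f1$adj_r2 - f2$adj_r2), 0.5)

  expect_error(predictionModelSpec("y", "s1",
                                   interactions = list(c("s1", "s9"))),
               "drawn from the SNP set")
})

test_that("cross-validation is deterministic and exact for noiseless data", {
  set.seed(31)
  n <- 300
  G <- cbind(x1 = rbinom(n, 2, 0.4))
  y <- 3 * G[, "x1"] + 1
  spec <- predictionModelSpec("y", "x1", covariates = character(0))
  cv <- crossValidatedR2(spec, G, y, NULL, nRep = 10, seed = 7)
  expect_equal(cv$r2, rep(100, 10), tolerance = 1e-9)
  cv2 <- crossValidatedR2(spec, G, y, NULL, nRep = 10, seed = 7)
  expect_identical(cv, cv2)
})

test_that("nested sub-models never out-fit the full model on noiseless data", {
  set.seed(32)
  n <- 500
  G <- sapply(1:12, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:12)
  y <- as.vector(G %*% c(2, rep(0.5, 5), rep(0.25, 6)))
  f6 <- fitPredictionModel(predictionModelSpec("y", colnames(G)[1:6],
                                               covariates = character(0)),
                           G, y, NULL)
  f12 <- fitPredictionModel(predictionModelSpec("y", colnames(G),
                                                covariates = character(0)),
                            G, y, NULL)
  expect_lte(f6$adj_r2, f12$adj_r2 + 1e-9)
  expect_equal(f12$adj_r2, 100, tolerance = 1e-8)
})

test_that("snpSummary reports MAF, call rate, HWE and ancestry information", {
  ch <- simulateCohort(cohortSpec(nIndividuals = 500, seed = 33))
  qc <- snpSummary(ch$genotypes, ch$covariates$population)
  expect_identical(nrow(qc), ncol(ch$genotypes))
  expect_true(all(qc$maf >= 0 & qc$maf <= 0.5))
  expect_true(all(qc$p_hwe > 0 & qc$p_hwe <= 1))
  expect_true(all(qc$in_ancestry >= 0))
  expect_true(all(qc$call_rate == 1))
})
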