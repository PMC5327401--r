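# Statistical genetics on minor-allele-dosage genotypes: QC summaries
# (MAF, exact HWE, LD r^2, informativeness for assignment), per-SNP
# association by partial correlation, SNP x SNP epistasis by nested-model
# F-tests, and cross-validated genotype-based prediction.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value
#' is the summed probability of all heterozygote configurations no more
#' probable than the observed one. Monomorphic SNPs return 1 by
#' convention.
#'
#' @param nAA,nAa,naa genotype counts (common homozygote, heterozygote,
#'   rare homozygote; the labelling of the homozygotes does not matter).
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' hweExactTest(25, 50, 25)   # perfect HWE proportions
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("counts must be >= 0", call. = FALSE)
  N <- nAA + nAa + naa
  if (N < 1L) stop("at least one individual required", call. = FALSE)
  nrare <- min(2 * nAA + nAa, 2 * naa + nAa)
  if (nrare == 0L) return(1)
  hs <- seq.int(nrare %% 2L, nrare, by = 2L)
  # P(h | N, nrare) on the log scale; constants in h cancel in the ratio
  # but are kept so probabilities are interpretable.
  homRare <- (nrare - hs) / 2
  homCommon <- N - hs - homRare
  logp <- lfactorial(N) - lfactorial(homRare) - lfactorial(hs) -
    lfactorial(homCommon) + hs * log(2) +
    lfactorial(nrare) + lfactorial(2 * N - nrare) - lfactorial(2 * N)
  pObs <- logp[hs == nAa]
  sum(exp(logp[logp <= pObs + 1e-12]))
}

#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of genotype dosages (phase-free composite
#' LD), pairwise-complete on missing genotypes.
#'
#' @param gA,gB aligned genotype dosage vectors (0/1/2, `NA` allowed).
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either
#'   vector is constant.
#' @export
ldR2 <- function(gA, gB) {
  if (length(gA) != length(gB))
    stop("genotype vectors must be aligned", call. = FALSE)
  ok <- !is.na(gA) & !is.na(gB)
  if (sum(ok) < 2L || stats::sd(gA[ok]) == 0 || stats::sd(gB[ok]) == 0) {
    warning("constant genotype vector: LD r^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(gA[ok], gB[ok])^2
}

.xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Informativeness for ancestry assignment
#'
#' Rosenberg's informativeness for assignment (In, in nats) of a biallelic
#' marker over K populations:
#' `In = sum_alleles [ -pbar log pbar + sum_pops (p_pop / K) log p_pop ]`
#' with `0 log 0 = 0` and `pbar` the unweighted mean allele frequency
#' across populations. Zero when all populations share the same allele
#' frequencies.
#'
#' @param g genotype dosage vector (0/1/2, `NA` allowed).
#' @param pop population labels aligned with `g`; at least 2 populations
#'   with at least one called genotype each.
#' @return In in nats (>= 0).
#' @export
ancestryInformativeness <- function(g, pop) {
  if (length(g) != length(pop))
    stop("genotypes and population labels must be aligned", call. = FALSE)
  ok <- !is.na(g) & !is.na(pop)
  pops <- unique(pop[ok])
  if (length(pops) < 2L)
    stop("at least 2 populations with called genotypes are required",
         call. = FALSE)
  pk <- vapply(pops, function(P) mean(g[ok & pop == P]) / 2, numeric(1L))
  K <- length(pk)
  In <- 0
  for (freqs in list(pk, 1 - pk)) {
    pbar <- mean(freqs)
    In <- In - .xlogx(pbar) + sum(.xlogx(freqs)) / K
  }
  max(In, 0)
}

# Covariate design matrix: intercept, age, sex, population dummies with
# the alphabetically first level as reference. `covariates` may be NULL
# (intercept only) or a data.frame with any of age/sex/population.
.covariateDesign <- function(covariates, n) {
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (is.null(covariates)) return(X)
  if (nrow(covariates) != n)
    stop("covariate table is not aligned with the data", call. = FALSE)
  if ("age" %in% names(covariates))
    X <- cbind(X, age = as.numeric(covariates$age))
  if ("sex" %in% names(covariates)) {
    s <- covariates$sex
    if (!is.numeric(s)) s <- as.numeric(factor(s)) - 1
    X <- cbind(X, sex = s)
  }
  if ("population" %in% names(covariates)) {
    f <- factor(covariates$population)
    if (nlevels(f) > 1L) {
      D <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(D) <- paste0("pop", levels(f)[-1L])
      X <- cbind(X, D)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  X
}

# rows with no missing value in any of the supplied pieces
.completeRows <- function(...) {
  pieces <- list(...)
  ok <- rep(TRUE, NROW(pieces[[1L]]))
  for (p in pieces) {
    if (is.null(p)) next
    ok <- ok & if (is.data.frame(p) || is.matrix(p))
      stats::complete.cases(p) else !is.na(p)
  }
  ok
}

.pFloor <- function(p) pmax(p, .Machine$double.xmin)

#' Per-SNP association by partial correlation
#'
#' Residualises the genotype dosage and the phenotype on the covariate
#' design (intercept, age, sex, population dummies), correlates the
#' residuals, and reports the partial variance explained
#' `r2 = 100 * r^2` (in percent) with the t-based p-value at
#' `n - 2 - k` degrees of freedom (k = covariate columns excluding the
#' intercept). `beta` is the genotype coefficient of the equivalent full
#' linear model (identical by Frisch-Waugh-Lovell).
#'
#' @param g genotype dosage vector (0/1/2).
#' @param y quantitative phenotype vector.
#' @param covariates optional `data.frame` with `age`, `sex`,
#'   `population` columns (any subset).
#' @param snpId,phenotypeName labels carried into the result.
#' @return One-row `data.frame`: `snp_id`, `phenotype`, `beta`, `r2`
#'   (percent), `p`, `n`.
#' @export
snpAssociation <- function(g, y, covariates = NULL, snpId = "snp",
                           phenotypeName = "phenotype") {
  ok <- .completeRows(g, y, covariates)
  g <- g[ok]; y <- y[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- length(g)
  X <- .covariateDesign(covariates, n)
  k <- ncol(X) - 1L
  if (n <= k + 2L)
    stop("too few observations for the covariate design", call. = FALSE)
  qrX <- qr(X)
  rg <- qr.resid(qrX, g)
  ry <- qr.resid(qrX, y)
  sg <- sum(rg^2)
  if (sg == 0) stop("genotype is constant after covariate adjustment",
                    call. = FALSE)
  r <- sum(rg * ry) / sqrt(sg * sum(ry^2))
  df <- n - 2L - k
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  data.frame(snp_id = snpId, phenotype = phenotypeName,
             beta = sum(rg * ry) / sg, r2 = 100 * r^2,
             p = .pFloor(2 * stats::pt(-abs(tt), df)), n = n,
             stringsAsFactors = FALSE)
}

#' Combined multi-SNP association model
#'
#' One multiple regression of the phenotype on all SNP dosages plus the
#' covariates. SNP columns that are exactly collinear with earlier
#' columns (e.g. a duplicated SNP) are dropped with a warning. Reports
#' each retained SNP's coefficient and t-test p-value plus the model's
#' adjusted R-squared (percent).
#'
#' @param G `n x m` genotype dosage matrix with SNP ids as column names.
#' @param y phenotype vector.
#' @param covariates optional covariate `data.frame`.
#' @return List of class `"CombinedAssociation"` with `snps` (per-SNP
#'   `data.frame`), `adj_r2` (percent), `r2` (percent), `n` and
#'   `dropped` (character).
#' @export
combinedAssociation <- function(G, y, covariates = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  ok <- .completeRows(G, y, covariates)
  G <- G[ok, , drop = FALSE]; y <- y[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- nrow(G)
  X <- cbind(.covariateDesign(covariates, n), G)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("dropping exactly collinear column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    qrX <- qr(X)
  }
  coefs <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  p <- ncol(X)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)[order(qrX$pivot)]
  tt <- coefs / se
  pv <- .pFloor(2 * stats::pt(-abs(tt), n - p))
  snpCols <- intersect(colnames(G), colnames(X))
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - rss / sstot
  structure(list(
    snps = data.frame(snp_id = snpCols, beta = coefs[snpCols],
                      p = pv[snpCols], row.names = NULL,
                      stringsAsFactors = FALSE),
    adj_r2 = 100 * (1 - (1 - r2) * (n - 1) / (n - p)),
    r2 = 100 * r2, n = n, dropped = dropped),
    class = "CombinedAssociation")
}

# qr fit returning the residual sum of squares, NA-free fast path for
# the interaction F-test and cross-validation loops.
.rss <- function(X, y) sum(qr.resid(qr(X), y)^2)

#' SNP x SNP interaction test (nested-model F-test)
#'
#' Fits the additive model
#' `Y ~ b0 + b1 X1 + b2 X2 + covariates` and the same model plus the
#' multiplicative interaction term `b3 X3`, `X3 = X1 * X2`, and compares
#' them with an F-test on one degree of freedom. Pairs whose product term
#' is collinear with the main effects (or identical SNPs) are flagged
#' untestable rather than tested.
#'
#' @param gA,gB aligned genotype dosage vectors.
#' @param y phenotype vector.
#' @param covariates optional covariate `data.frame`.
#' @param snpA,snpB,phenotypeName labels carried into the result.
#' @return One-row `data.frame`: `snp_a`, `snp_b`, `phenotype`, `beta3`,
#'   `f_stat`, `p`, `n`, `untestable`.
#' @export
interactionTest <- function(gA, gB, y, covariates = NULL, snpA = "snp_a",
                            snpB = "snp_b", phenotypeName = "phenotype") {
  ok <- .completeRows(gA, gB, y, covariates)
  gA <- gA[ok]; gB <- gB[ok]; y <- y[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- length(y)
  out <- data.frame(snp_a = snpA, snp_b = snpB, phenotype = phenotypeName,
                    beta3 = NA_real_, f_stat = NA_real_, p = NA_real_,
                    n = n, untestable = TRUE, stringsAsFactors = FALSE)
  if (stats::sd(gA) == 0 || stats::sd(gB) == 0) return(out)
  X0 <- cbind(.covariateDesign(covariates, n), gA = gA, gB = gB)
  X1 <- cbind(X0, gAxB = gA * gB)
  qr1 <- qr(X1)
  if (qr1$rank < ncol(X1)) return(out)
  p1 <- ncol(X1)
  rss0 <- .rss(X0, y)
  res1 <- qr.resid(qr1, y)
  rss1 <- sum(res1^2)
  f <- max(0, (rss0 - rss1)) / (rss1 / (n - p1))
  out$beta3 <- qr.coef(qr1, y)[["gAxB"]]
  out$f_stat <- f
  out$p <- .pFloor(stats::pf(f, 1, n - p1, lower.tail = FALSE))
  out$untestable <- FALSE
  out
}

#' Scan all SNP pairs for epistasis
#'
#' Runs [interactionTest()] for every SNP pair and phenotype, excluding
#' pairs in strong LD (dosage `r^2` above `ldThreshold`, default 0.8) as
#' is standard for near-redundant markers, and flags Bonferroni-passing
#' results at `alpha / familySize`.
#'
#' @param G genotype dosage matrix (SNP ids as column names).
#' @param phenotypes `data.frame` or matrix of quantitative phenotypes
#'   (one column each).
#' @param covariates optional covariate `data.frame`.
#' @param ldThreshold LD exclusion threshold on dosage r-squared.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param familySize Bonferroni family size; default = pairs tested x
#'   phenotypes.
#' @return `data.frame` of [interactionTest()] rows (plus
#'   `passes_bonferroni`), sorted by p-value; excluded high-LD pairs are
#'   absent.
#' @export
interactionScan <- function(G, phenotypes, covariates = NULL,
                            ldThreshold = 0.8, alpha = 0.05,
                            familySize = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  phenotypes <- as.data.frame(phenotypes)
  pairs <- utils::combn(colnames(G), 2L)
  keep <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    r2 <- suppressWarnings(ldR2(G[, pairs[1L, k]], G[, pairs[2L, k]]))
    keep[k] <- is.na(r2) || r2 <= ldThreshold
  }
  pairs <- pairs[, keep, drop = FALSE]
  nTests <- ncol(pairs) * ncol(phenotypes)
  if (is.null(familySize)) familySize <- nTests
  if (familySize < nTests)
    stop("familySize must be at least the number of tests performed",
         call. = FALSE)
  out <- NULL
  for (ph in names(phenotypes)) {
    for (k in seq_len(ncol(pairs))) {
      out <- rbind(out, interactionTest(
        G[, pairs[1L, k]], G[, pairs[2L, k]], phenotypes[[ph]],
        covariates, snpA = pairs[1L, k], snpB = pairs[2L, k],
        phenotypeName = ph))
    }
  }
  out$passes_bonferroni <- !is.na(out$p) & out$p < alpha / familySize
  attr(out, "familySize") <- familySize
  attr(out, "alpha") <- alpha
  out[order(out$untestable, out$p), , drop = FALSE]
}

#' Specify a genotype-based prediction model
#'
#' Describes the linear prediction model
#' `Y ~ b0 + sum_j b_j SNP_j + sum_pairs b3 SNPa*SNPb + age + sex + pop`.
#'
#' @param phenotype name of the response phenotype.
#' @param snps character vector of SNP ids entering as additive dosages.
#' @param interactions list of character(2) SNP-id pairs entering as
#'   product terms; every member must be in `snps`.
#' @param covariates covariate names to include (subset of
#'   `c("age", "sex", "population")`).
#' @return List of class `"PredictionModelSpec"`.
#' @export
predictionModelSpec <- function(phenotype, snps, interactions = list(),
                                covariates = c("age", "sex",
                                               "population")) {
  for (pr in interactions) {
    if (length(pr) != 2L || !all(pr %in% snps))
      stop("interaction pairs must be drawn from the SNP set",
           call. = FALSE)
  }
  structure(list(phenotype = phenotype, snps = snps,
                 interactions = interactions, covariates = covariates),
            class = "PredictionModelSpec")
}

.designForSpec <- function(spec, G, covariates, n) {
  cv <- if (is.null(covariates)) NULL else
    covariates[, intersect(spec$covariates, names(covariates)),
               drop = FALSE]
  X <- .covariateDesign(if (is.null(cv) || ncol(cv) == 0L) NULL else cv, n)
  Gs <- as.matrix(G[, spec$snps, drop = FALSE])
  X <- cbind(X, Gs)
  for (pr in spec$interactions) {
    X <- cbind(X, G[, pr[1L]] * G[, pr[2L]])
    colnames(X)[ncol(X)] <- paste(pr, collapse = "_x_")
  }
  X
}

#' Fit a prediction model by ordinary least squares
#'
#' @param spec a [predictionModelSpec()].
#' @param G genotype dosage matrix.
#' @param y response phenotype vector (aligned with `G`).
#' @param covariates covariate `data.frame`.
#' @return List of class `"PredictionModelFit"` with `coefficients`,
#'   `r2` and `adj_r2` (percent), `n`, `spec`.
#' @export
fitPredictionModel <- function(spec, G, y, covariates = NULL) {
  ok <- .completeRows(as.matrix(G[, spec$snps, drop = FALSE]), y,
                      covariates)
  G <- G[ok, , drop = FALSE]; y <- y[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- length(y)
  X <- .designForSpec(spec, G, covariates, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient prediction design; drop collinear terms",
         call. = FALSE)
  coefs <- qr.coef(qrX, y)
  rss <- sum(qr.resid(qrX, y)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - rss / sstot
  p <- ncol(X) - 1L
  structure(list(coefficients = coefs, r2 = 100 * r2,
                 adj_r2 = 100 * (1 - (1 - r2) * (n - 1) / (n - p - 1L)),
                 n = n, spec = spec),
            class = "PredictionModelFit")
}

#' Cross-validated prediction accuracy
#'
#' Repeated randomized train/holdout evaluation: for each repeat a
#' seeded random `trainFraction` of the samples is used to fit the model
#' and the holdout coefficient of determination
#' `R^2 = 100 * (1 - SS_res / SS_tot)` is computed on the rest. Defaults
#' follow standard practice for this analysis: 100 repeats with 2/3
#' training fraction.
#'
#' @inheritParams fitPredictionModel
#' @param nRep number of randomized train/holdout repeats.
#' @param trainFraction fraction of samples used for training.
#' @param seed integer seed making the split sequence reproducible.
#' @return List of class `"PredictionResult"`: `mean_r2`, `q05`, `q95`
#'   (percent), `r2` (per-repeat values), `n_rep`, `train_fraction`,
#'   `seed`, `spec`.
#' @export
crossValidatedR2 <- function(spec, G, y, covariates = NULL, nRep = 100L,
                             trainFraction = 2 / 3, seed = 1L) {
  stopifnot(nRep >= 1L, trainFraction > 0, trainFraction < 1)
  ok <- .completeRows(as.matrix(G[, spec$snps, drop = FALSE]), y,
                      covariates)
  G <- G[ok, , drop = FALSE]; y <- y[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  n <- length(y)
  X <- .designForSpec(spec, G, covariates, n)
  nTrain <- round(trainFraction * n)
  r2s <- .withFixedSeed(seed, function() {
    vapply(seq_len(nRep), function(i) {
      idx <- sample.int(n, nTrain)
      yHold <- y[-idx]
      sstot <- sum((yHold - mean(yHold))^2)
      if (sstot == 0) {
        warning("holdout with zero phenotype variance; repeat skipped",
                call. = FALSE)
        return(NA_real_)
      }
      cf <- qr.coef(qr(X[idx, , drop = FALSE]), y[idx])
      cf[is.na(cf)] <- 0
      pred <- X[-idx, , drop = FALSE] %*% cf
      100 * (1 - sum((yHold - pred)^2) / sstot)
    }, numeric(1L))
  })
  r2s <- r2s[!is.na(r2s)]
  structure(list(mean_r2 = mean(r2s),
                 q05 = unname(stats::quantile(r2s, 0.05)),
                 q95 = unname(stats::quantile(r2s, 0.95)),
                 r2 = r2s, n_rep = length(r2s),
                 train_fraction = trainFraction, seed = seed,
                 spec = spec),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf(
    "Cross-validated prediction of '%s': mean R2 = %.2f%% (%.2f, %.2f), %d repeats\n",
    x$spec$phenotype, x$mean_r2, x$q05, x$q95, x$n_rep))
  invisible(x)
}

#' Per-SNP quality-control summary
#'
#' Minor-allele frequency, call rate, exact HWE p-value and (when
#' population labels are supplied) informativeness for ancestry
#' assignment for every SNP of a genotype matrix.
#'
#' @param G genotype dosage matrix (SNP ids as column names).
#' @param pop optional population labels (one per row of `G`).
#' @return `data.frame` with columns `snp_id`, `maf`, `call_rate`,
#'   `p_hwe`, and `in_ancestry` when `pop` is given.
#' @export
snpSummary <- function(G, pop = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  out <- do.call(rbind, lapply(colnames(G), function(s) {
    g <- G[, s]
    ok <- !is.na(g)
    f <- mean(g[ok]) / 2
    counts <- tabulate(g[ok] + 1L, 3L)
    data.frame(snp_id = s, maf = min(f, 1 - f),
               call_rate = mean(ok),
               p_hwe = hweExactTest(counts[1L], counts[2L], counts[3L]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(pop))
    out$in_ancestry <- vapply(colnames(G), function(s)
      ancestryInformativeness(G[, s], pop), numeric(1L))
  out
}
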