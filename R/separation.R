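# Quantifier inter-correlation and category-separation analysis.

#' Pairwise Pearson correlations between colour quantifiers
#'
#' Pearson r and two-sided p-values (t distribution, n - 2 df) for every
#' pair of quantifier columns, with pairwise-complete deletion of missing
#' values. Constant variables yield `NA` with a warning.
#'
#' @param table a `data.frame` of quantifications (e.g. rows from
#'   [quantifyEye()]) with at least 3 complete rows.
#' @param variables character vector of columns to correlate; default:
#'   all numeric quantifier columns present.
#' @return A list of class `"CorrelationMatrix"` with elements `r`, `p`
#'   (symmetric matrices, unit/zero diagonal), `n` (pairwise sample
#'   counts) and `variables`.
#' @export
pairwiseCorrelations <- function(table, variables = NULL) {
  if (is.null(variables)) {
    std <- c("p_non", "p_pheo", "p_eu", "mean_h", "mean_s", "lum_l",
             "colour_c", "l_star", "a_star", "b_star", "pie", "t_index")
    variables <- intersect(std, names(table))
    if (length(variables) < 2L)
      variables <- names(table)[vapply(table, is.numeric, logical(1L))]
  }
  X <- as.matrix(table[, variables, drop = FALSE])
  if (sum(stats::complete.cases(X)) < 3L)
    stop("at least 3 complete rows are required", call. = FALSE)
  k <- length(variables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  constant <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(X[, c(i, j)])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (nij < 3L) next
    if (stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) {
      constant <- union(constant,
                        variables[c(i, j)][c(stats::sd(X[ok, i]) == 0,
                                             stats::sd(X[ok, j]) == 0)])
      next
    }
    rij <- stats::cor(X[ok, i], X[ok, j])
    r[i, j] <- r[j, i] <- rij
    tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = nij - 2)
  }
  diag(n) <- colSums(!is.na(X))
  if (length(constant))
    warning("constant variable(s), correlations undefined: ",
            paste(constant, collapse = ", "), call. = FALSE)
  structure(list(r = r, p = p, n = n, variables = variables),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pairwise Pearson correlations over %d quantifiers\n",
              length(x$variables)))
  print(round(x$r, digits))
  invisible(x)
}

#' Hellinger distance between two empirical distributions
#'
#' Shared-grid histogram estimator: both samples are binned on an
#' identical grid spanning the pooled range, normalised to probabilities
#' `p`, `q`, and `HD = sqrt(1 - sum(sqrt(p * q)))`. The estimator is 0 for
#' identical samples and exactly 1 for samples with disjoint support on
#' the grid.
#'
#' @param a,b numeric vectors (1-D) or matrices with matching column
#'   count (1 or 2 dimensions), both non-empty.
#' @param bins bins per dimension; default 64 in 1-D and 32 in 2-D.
#' @param range optional `2 x d` matrix of per-dimension (min, max) grid
#'   limits; default: pooled min-max of both samples.
#' @return Scalar Hellinger distance in `[0, 1]`.
#' @examples
#' set.seed(1)
#' hellingerDistance(rnorm(1e4), rnorm(1e4, mean = 1))
#' @export
hellingerDistance <- function(a, b, bins = NULL, range = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("samples must have the same dimensionality", call. = FALSE)
  d <- ncol(a)
  if (!d %in% 1:2)
    stop("only 1- or 2-dimensional samples are supported", call. = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (is.null(bins)) bins <- if (d == 1L) 64L else 32L
  bins <- rep_len(as.integer(bins), d)
  idxA <- matrix(0L, nrow(a), d); idxB <- matrix(0L, nrow(b), d)
  for (j in seq_len(d)) {
    rng <- if (is.null(range)) c(min(a[, j], b[, j]), max(a[, j], b[, j]))
           else range[, j]
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1L], rng[2L], length.out = bins[j] + 1L)
    f <- function(x) pmin(pmax(findInterval(x, br, rightmost.closed = TRUE),
                               1L), bins[j])
    idxA[, j] <- f(a[, j]); idxB[, j] <- f(b[, j])
  }
  cellA <- idxA[, 1L]; cellB <- idxB[, 1L]
  if (d == 2L) {
    cellA <- cellA + bins[1L] * (idxA[, 2L] - 1L)
    cellB <- cellB + bins[1L] * (idxB[, 2L] - 1L)
  }
  ncell <- prod(bins)
  p <- tabulate(cellA, ncell) / nrow(a)
  q <- tabulate(cellB, ncell) / nrow(b)
  bc <- sum(sqrt(p * q))
  sqrt(max(0, 1 - bc))
}

#' The ten standard colour subspaces
#'
#' The two-dimensional pigment-proportion, H/S, melanin-index/colour-score,
#' Lab-component subspaces and the one-dimensional PIE score and T-index in
#' which category separation is routinely assessed.
#'
#' @return Named list of character vectors of quantifier column names.
#' @export
defaultColourSubspaces <- function() {
  list("pheomelanin_vs_eumelanin" = c("p_pheo", "p_eu"),
       "nonpigmented_vs_pheomelanin" = c("p_non", "p_pheo"),
       "nonpigmented_vs_eumelanin" = c("p_non", "p_eu"),
       "hue_vs_saturation" = c("mean_h", "mean_s"),
       "luminosity_vs_colourscore" = c("lum_l", "colour_c"),
       "astar_vs_bstar" = c("a_star", "b_star"),
       "lstar_vs_astar" = c("l_star", "a_star"),
       "lstar_vs_bstar" = c("l_star", "b_star"),
       "pie" = "pie",
       "t_index" = "t_index")
}

#' Category-separation table (Hellinger distances per subspace)
#'
#' For every requested quantifier subspace and every pair of manual
#' eye-colour categories, computes the Hellinger distance between the two
#' category clouds on a shared histogram grid, and flags the
#' best-separating subspace per category pair.
#'
#' @param table quantification `data.frame` including a category column.
#' @param categoryColumn name of the category column (default
#'   `"category"`).
#' @param subspaces named list of 1- or 2-column subspaces (default
#'   [defaultColourSubspaces()], restricted to available columns).
#' @param minN minimum rows per category (default 30); pairs involving a
#'   smaller category are skipped with a warning.
#' @param bins bins per dimension passed to [hellingerDistance()].
#' @return `data.frame` with columns `subspace`, `category_a`,
#'   `category_b`, `hd`, `n_a`, `n_b`, `best` (logical: best subspace for
#'   that pair).
#' @export
categorySeparationTable <- function(table, categoryColumn = "category",
                                    subspaces = NULL, minN = 30L,
                                    bins = NULL) {
  if (!categoryColumn %in% names(table))
    stop(sprintf("column '%s' not found", categoryColumn), call. = FALSE)
  if (is.null(subspaces)) {
    subspaces <- defaultColourSubspaces()
    subspaces <- subspaces[vapply(subspaces,
                                  function(v) all(v %in% names(table)),
                                  logical(1L))]
  }
  cats <- table[[categoryColumn]]
  keep <- !is.na(cats)
  table <- table[keep, , drop = FALSE]; cats <- cats[keep]
  lv <- sort(unique(cats))
  counts <- table(cats)
  usable <- names(counts)[counts >= minN]
  if (length(usable) < 2L)
    stop("at least 2 categories with >= minN rows are required",
         call. = FALSE)
  skipped <- setdiff(lv, usable)
  if (length(skipped))
    warning("categories below minN skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  pairs <- utils::combn(usable, 2L)
  out <- NULL
  for (s in names(subspaces)) {
    vars <- subspaces[[s]]
    for (k in seq_len(ncol(pairs))) {
      ca <- pairs[1L, k]; cb <- pairs[2L, k]
      A <- as.matrix(table[cats == ca, vars, drop = FALSE])
      B <- as.matrix(table[cats == cb, vars, drop = FALSE])
      hd <- hellingerDistance(A, B, bins = bins)
      out <- rbind(out, data.frame(subspace = s, category_a = ca,
                                   category_b = cb, hd = hd,
                                   n_a = nrow(A), n_b = nrow(B),
                                   stringsAsFactors = FALSE))
    }
  }
  out$best <- FALSE
  for (k in seq_len(ncol(pairs))) {
    sel <- out$category_a == pairs[1L, k] & out$category_b == pairs[2L, k]
    out$best[sel][which.max(out$hd[sel])] <- TRUE
  }
  out
}
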