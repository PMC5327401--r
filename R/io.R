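# Tabular I/O: genotype matrices (CSV or VCF), covariate tables, and the
# versioned CSV reports written by the command wrappers.

#' Read a genotype matrix
#'
#' CSV input: one `sample_id` column plus one column per SNP holding
#' dosages 0/1/2 (`NA` = missing). VCF input (requires the `vcfR`
#' package): biallelic SNPs; genotypes are converted to counts of the
#' minor allele (the less frequent allele in the file).
#'
#' @param path genotype file (`.csv`, `.vcf` or `.vcf.gz`).
#' @param format `"auto"` (by extension), `"csv"` or `"vcf"`.
#' @return Integer matrix (individuals x SNPs) with sample ids as row
#'   names and SNP ids as column names.
#' @export
readGenotypes <- function(path, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "csv"
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (!"sample_id" %in% names(tab))
      stop("genotype CSV must contain a 'sample_id' column", call. = FALSE)
    G <- as.matrix(tab[, setdiff(names(tab), "sample_id"), drop = FALSE])
    storage.mode(G) <- "integer"
    rownames(G) <- tab$sample_id
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF genotypes requires the 'vcfR' package",
           call. = FALSE)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    alt <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    alt[clean == "0/0"] <- 0L
    alt[clean %in% c("0/1", "1/0")] <- 1L
    alt[clean == "1/1"] <- 2L
    G <- t(alt)
    # recode to minor-allele counts where the ALT allele is the major one
    for (j in seq_len(ncol(G))) {
      f <- mean(G[, j], na.rm = TRUE) / 2
      if (!is.na(f) && f > 0.5) G[, j] <- 2L - G[, j]
    }
    ids <- vcfR::getID(v)
    colnames(G) <- ifelse(is.na(ids) | ids == ".",
                          paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v)),
                          ids)
  }
  bad <- G[!is.na(G)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    stop("genotype dosages must lie in {0, 1, 2}", call. = FALSE)
  G
}

#' Read a covariate table
#'
#' CSV keyed by `sample_id` with columns `age` (years, > 0), `sex`
#' (0/1 or two character levels, coded 0/1 alphabetically) and
#' `population` (categorical).
#'
#' @param path covariate CSV path.
#' @return `data.frame` with `sample_id`, numeric `age` and `sex`, and
#'   character `population`.
#' @export
readCovariates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "age", "sex", "population"), names(tab))
  if (length(miss))
    stop("covariate CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(tab$sex))
    tab$sex <- as.numeric(factor(tab$sex)) - 1
  if (any(tab$age <= 0, na.rm = TRUE))
    stop("age must be positive", call. = FALSE)
  tab$population <- as.character(tab$population)
  tab
}

# Versioned CSV report: a comment header with the package version and a
# hash of the resolved configuration, then the data.
.writeReport <- function(df, path, config = NULL) {
  cfg <- paste(deparse(config), collapse = " ")
  tf <- tempfile(); writeLines(cfg, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  version <- as.character(utils::packageVersion("IrisPheno"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# IrisPheno %s config %s", version, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a report CSV written by the command wrappers
#'
#' @param path report CSV path (comment header lines are skipped).
#' @return `data.frame`.
#' @export
readReport <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
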