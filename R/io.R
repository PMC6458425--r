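# Plain-text input/output for the package's two data dialects:
# tab-separated GWAS summary statistics and cohort directories.

SUMSTATS_COLS <- c("snp", "effect_allele", "other_allele", "eaf", "beta",
                   "se", "pval", "n", "info")

#' Read and write GWAS summary statistics
#'
#' The dialect is tab-separated text with header columns `snp`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `info`.
#' Effect sizes for binary traits are log odds ratios; an `or` column, if
#' present instead of `beta`, is converted to log scale on ingest (SEs are
#' assumed to already be on the log scale, as is conventional).
#'
#' @param x a summary-statistics data.frame.
#' @param path file path.
#' @return `read_sumstats()` returns a validated data.frame;
#'   `write_sumstats()` returns `path` invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(all(SUMSTATS_COLS %in% names(x)))
  utils::write.table(x[SUMSTATS_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("or" %in% names(x) && !"beta" %in% names(x)) {
    x$beta <- log(x$or)
    x$or <- NULL
  }
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, "info"), names(x))
  if (length(missing_cols))
    stop("summary-statistics file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"info" %in% names(x)) x$info <- NA_real_
  validate_sumstats(x)
  x[SUMSTATS_COLS]
}

validate_sumstats <- function(x) {
  if (any(x$se <= 0, na.rm = TRUE)) stop("summary statistics contain se <= 0")
  if (any(x$eaf <= 0 | x$eaf >= 1, na.rm = TRUE))
    stop("summary statistics contain eaf outside (0,1)")
  if (any(x$effect_allele == x$other_allele))
    stop("summary statistics contain records with identical alleles")
  invisible(x)
}

#' Read and write cohort directories
#'
#' A cohort directory holds `genotypes.tsv` (individuals in rows, one column
#' per SNP, dosage values 0-2 or empty for missing), `phenotypes.tsv` (keyed
#' by `iid`) and `snps.tsv` (per-SNP allele labels).
#'
#' @param cohort a `"cohort_table"` object as returned by [gen_cohort()].
#' @param dir directory path (created if absent).
#' @return `read_cohort()` returns a `"cohort_table"`; `write_cohort()`
#'   returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- data.frame(iid = cohort$phenotypes$iid, cohort$dosages,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(geno, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$snp_info, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  geno <- utils::read.delim(file.path(dir, "genotypes.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  phen <- utils::read.delim(file.path(dir, "phenotypes.tsv"),
                            stringsAsFactors = FALSE)
  snps <- utils::read.delim(file.path(dir, "snps.tsv"),
                            stringsAsFactors = FALSE)
  stopifnot(identical(geno$iid, phen$iid))
  dos <- as.matrix(geno[setdiff(names(geno), "iid")])
  storage.mode(dos) <- "double"
  structure(list(dosages = dos, snp_info = snps, phenotypes = phen),
            class = "cohort_table")
}
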