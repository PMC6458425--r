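# GWAS engine: phenotype derivation, per-SNP covariate-adjusted association,
# and variant filtering.

#' Derive analysis phenotypes from raw cohort measures
#'
#' Adds `childless` (1 iff `number_of_children == 0`); censors lifetime
#' sexual-partner counts strictly above their empirical 99th percentile to
#' missing; and adds `top_partners` (1 iff the trimmed partner count is at or
#' above the empirical 90th-percentile cut).  The cut actually used is
#' recorded in the `"partner_cuts"` attribute of the phenotype table.
#'
#' @param raw a `"cohort_table"` or a phenotype data.frame containing
#'   `number_of_children` (and optionally `n_sexual_partners`).
#' @return the input with derived columns added (same class as `raw`).
#' @examples
#' cohort <- gen_cohort(sim_config(n_individuals = 200, n_snps = 5))
#' ph <- derive_phenotypes(cohort)$phenotypes
#' table(ph$childless)
#' @export
derive_phenotypes <- function(raw) {
  is_cohort <- inherits(raw, "cohort_table")
  ph <- if (is_cohort) raw$phenotypes else raw
  stopifnot("number_of_children" %in% names(ph))
  if (any(ph$n_sexual_partners < 0, na.rm = TRUE))
    stop("partner counts must be non-negative")
  ph$childless <- as.integer(ph$number_of_children == 0)
  partners <- ph$n_sexual_partners
  if (is.null(partners) || all(is.na(partners))) {
    warning("all partner values missing; top_partners not derived")
  } else {
    p99 <- stats::quantile(partners, 0.99, na.rm = TRUE, names = FALSE)
    partners[!is.na(partners) & partners > p99] <- NA_real_
    top_cut <- stats::quantile(partners, 0.90, na.rm = TRUE, names = FALSE)
    ph$n_sexual_partners <- partners
    ph$top_partners <- as.integer(partners >= top_cut)
    attr(ph, "partner_cuts") <- c(p99 = p99, top_cut = top_cut)
  }
  if (is_cohort) {
    raw$phenotypes <- ph
    raw
  } else ph
}

# single weighted/unweighted least-squares (or logistic) fit via base QR,
# returning the dosage coefficient and its SE
fit_snp <- function(X, y, model) {
  p <- ncol(X)
  if (model == "linear") {
    fit <- stats::lm.fit(X, y)
    if (fit$rank < p) return(NULL)
    res <- fit$residuals
    sigma2 <- sum(res^2) / (length(y) - p)
    pos <- which(fit$qr$pivot == p)  # dose column under QR pivoting
    cov_last <- chol2inv(qr.R(fit$qr))[pos, pos]
    c(beta = unname(fit$coefficients[p]), se = sqrt(sigma2 * cov_last))
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    if (!fit$converged || fit$rank < p) return(NULL)
    W <- fit$weights
    cov <- tryCatch(chol2inv(chol(crossprod(X * sqrt(W)))),
                    error = function(e) NULL)
    if (is.null(cov)) return(NULL)
    c(beta = unname(fit$coefficients[p]), se = sqrt(cov[p, p]))
  }
}

#' Per-SNP covariate-adjusted association
#'
#' Regresses the phenotype on each SNP's dosage plus covariates, one SNP at a
#' time, by ordinary least squares (`model = "linear"`) or logistic
#' regression (`model = "logistic"`, returning log odds ratios).  Individuals
#' with a missing phenotype or any missing covariate are dropped for the
#' whole analysis (complete-case); individuals with a missing dosage are
#' dropped per SNP.  P-values are two-sided Wald (normal approximation).
#'
#' @param cohort a `"cohort_table"`.
#' @param phenotype name of the phenotype column.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param model `"linear"` or `"logistic"`.
#' @param exclude_cases drop individuals flagged as disorder cases before
#'   fitting (sensitivity rerun).
#' @return a summary-statistics data.frame (one row per SNP: `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `info`).  SNPs with zero dosage variance or non-converged fits keep
#'   their row with missing `beta`/`se` and raise a warning.
#' @examples
#' cohort <- gen_cohort(sim_config(n_individuals = 500, n_snps = 10))
#' assoc <- run_association(cohort, "number_of_children",
#'                          paste0("pc", 1:10), "linear")
#' @export
run_association <- function(cohort, phenotype, covariates = character(),
                            model = c("linear", "logistic"),
                            exclude_cases = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "cohort_table"))
  ph <- cohort$phenotypes
  stopifnot(phenotype %in% names(ph), all(covariates %in% names(ph)))
  y <- ph[[phenotype]]
  if (model == "logistic" && !all(y %in% c(0, 1, NA)))
    stop("logistic model requires a binary phenotype")
  covmat <- if (length(covariates))
    as.matrix(ph[covariates]) else matrix(nrow = nrow(ph), ncol = 0)
  keep0 <- !is.na(y) & stats::complete.cases(covmat)
  if (exclude_cases && "case_flag" %in% names(ph))
    keep0 <- keep0 & ph$case_flag == 0
  snps <- cohort$snp_info
  m <- nrow(snps)
  out <- data.frame(snp = snps$snp, effect_allele = snps$counted_allele,
                    other_allele = snps$other_allele, eaf = NA_real_,
                    beta = NA_real_, se = NA_real_, pval = NA_real_,
                    n = NA_integer_, info = 1, stringsAsFactors = FALSE)
  n_failed <- 0L
  for (j in seq_len(m)) {
    d <- cohort$dosages[, j]
    keep <- keep0 & !is.na(d)
    nj <- sum(keep)
    out$n[j] <- nj
    if (nj < ncol(covmat) + 3L) { n_failed <- n_failed + 1L; next }
    dj <- d[keep]
    out$eaf[j] <- mean(dj) / 2
    if (stats::var(dj) == 0) { n_failed <- n_failed + 1L; next }
    X <- cbind(1, covmat[keep, , drop = FALSE], dose = dj)
    est <- fit_snp(X, y[keep], model)
    if (is.null(est)) { n_failed <- n_failed + 1L; next }
    out$beta[j] <- est["beta"]
    out$se[j] <- est["se"]
    out$pval[j] <- 2 * stats::pnorm(-abs(est["beta"] / est["se"]))
  }
  if (n_failed > 0)
    warning(n_failed, " SNP(s) returned no estimate ",
            "(zero dosage variance, rank deficiency or non-convergence)")
  out
}

#' Filter variants on minor allele frequency and imputation quality
#'
#' `mode = "flat"` keeps records with MAF (i.e. `min(eaf, 1 - eaf)`) above
#' 0.01 and imputation info above 0.8.  `mode = "graded"` applies a banded
#' rule that demands higher imputation quality for rarer variants:
#' info > 0.3 for MAF > 3%; info > 0.6 for MAF 1-3%; info > 0.8 for
#' MAF 0.5-1%; info > 0.9 for MAF 0.1-0.5%; MAF below 0.1% is always
#' dropped.  Records with missing info are dropped (conservative) and
#' counted.  The operation is idempotent; per-rule drop counts are attached
#' as the `"filter_log"` attribute.
#'
#' @param assocs a summary-statistics data.frame.
#' @param mode `"flat"` or `"graded"`.
#' @return the surviving records.
#' @examples
#' x <- data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
#'                 eaf = 0.02, beta = 0.1, se = 0.01, pval = 1e-6,
#'                 n = 1000, info = 0.65)
#' nrow(filter_variants(x, "graded"))  # kept: band 1-3% requires info > 0.6
#' @export
filter_variants <- function(assocs, mode = c("flat", "graded")) {
  mode <- match.arg(mode)
  maf <- pmin(assocs$eaf, 1 - assocs$eaf)
  info <- assocs$info
  info_missing <- is.na(info)
  keep <- if (mode == "flat") {
    !info_missing & maf > 0.01 & info > 0.8
  } else {
    !info_missing & (
      (maf > 0.03 & info > 0.3) |
      (maf > 0.01 & maf <= 0.03 & info > 0.6) |
      (maf > 0.005 & maf <= 0.01 & info > 0.8) |
      (maf > 0.001 & maf <= 0.005 & info > 0.9))
  }
  keep[is.na(keep)] <- FALSE
  out <- assocs[keep, , drop = FALSE]
  attr(out, "filter_log") <- c(
    input = nrow(assocs), kept = sum(keep),
    dropped_missing_info = sum(info_missing),
    dropped_maf_info = sum(!keep & !info_missing))
  out
}
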