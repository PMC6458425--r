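# Genetic-score nonlinearity machinery: unweighted additive score, quantile
# fitness curves, cumulative tail-removal regression scans and quadratic
# (optionally sex-stratified) fits.

# least-squares fit via QR, returning coefficients, SEs and the full
# covariance matrix (normal-approximation inference)
ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  p <- ncol(X)
  if (fit$rank < p) stop("collinear design: fit failure")
  sigma2 <- sum(fit$residuals^2) / (length(y) - p)
  R <- qr.R(fit$qr)
  vcov <- chol2inv(R) * sigma2
  # chol2inv(R) is ordered by the QR pivot; restore original column order
  piv <- fit$qr$pivot
  vcov[piv, piv] <- vcov
  list(coef = fit$coefficients, se = sqrt(diag(vcov)), vcov = vcov,
       n = length(y))
}

#' Additive unweighted genetic score
#'
#' Sums risk-allele dosages over SNPs, with missing dosages replaced by the
#' cohort mean dosage of that SNP (after orientation to the risk allele).
#' Dosages counted on the non-risk allele are reversed (`2 - d`) before
#' summation.  SNPs with no observed dosages at all are excluded with a
#' warning.
#'
#' @param cohort a `"cohort_table"`.
#' @param risk_alleles per-SNP risk-allele labels; defaults to
#'   `cohort$snp_info$risk_allele`.
#' @return a numeric per-individual score.
#' @examples
#' cohort <- gen_cohort(sim_config(n_individuals = 200, n_snps = 10))
#' score <- build_unweighted_score(cohort)
#' @export
build_unweighted_score <- function(cohort, risk_alleles = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(risk_alleles)) risk_alleles <- cohort$snp_info$risk_allele
  stopifnot(length(risk_alleles) == ncol(cohort$dosages))
  d <- cohort$dosages
  reversed <- risk_alleles != cohort$snp_info$counted_allele
  if (any(reversed))
    d[, reversed] <- 2 - d[, reversed, drop = FALSE]
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " SNP(s) entirely missing; excluded from score")
    d <- d[, !all_missing, drop = FALSE]
  }
  means <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) {
    d[is.na(d[, j]), j] <- means[j]
  }
  rowSums(d)
}

#' Mean outcome across score quantile bins
#'
#' Bins individuals with a non-missing outcome into `q` equal-count groups
#' by empirical score quantiles (ties broken by stable rank order, bin
#' counts equal up to 1) and returns each bin's mean outcome with a
#' normal-approximation 95% CI.  The transposed view (outcome on the x-axis,
#' mean score per outcome bin) is returned alongside.
#'
#' @param score per-individual genetic score.
#' @param outcome per-individual outcome (missing values dropped).
#' @param q number of bins (5 for quintiles, 10 for deciles).
#' @return a list with data.frames `score_bins` (`bin`, `n`, `score_mean`,
#'   `outcome_mean`, `se`, `ci_low`, `ci_high`) and `outcome_bins` (the
#'   transposed view).
#' @export
quantile_summary <- function(score, outcome, q = 5L) {
  stopifnot(length(score) == length(outcome))
  keep <- !is.na(outcome) & !is.na(score)
  s <- score[keep]; y <- outcome[keep]
  if (q > length(unique(s)))
    stop("q exceeds the number of distinct score values")
  bin_by <- function(x) {
    n <- length(x)
    sizes <- diff(round(seq(0, n, length.out = q + 1)))
    bins <- integer(n)
    bins[order(x)] <- rep(seq_len(q), times = sizes)  # stable rank order
    bins
  }
  summarize <- function(bins, xval, yval) {
    out <- do.call(rbind, lapply(seq_len(q), function(b) {
      i <- bins == b
      m <- mean(yval[i]); se <- stats::sd(yval[i]) / sqrt(sum(i))
      data.frame(bin = b, n = sum(i), x_mean = mean(xval[i]),
                 y_mean = m, se = se,
                 ci_low = m - 1.96 * se, ci_high = m + 1.96 * se)
    }))
    out
  }
  sb <- summarize(bin_by(s), s, y)
  names(sb)[names(sb) == "x_mean"] <- "score_mean"
  names(sb)[names(sb) == "y_mean"] <- "outcome_mean"
  ob <- summarize(bin_by(y), y, s)
  names(ob)[names(ob) == "x_mean"] <- "outcome_mean"
  names(ob)[names(ob) == "y_mean"] <- "score_mean"
  list(score_bins = sb, outcome_bins = ob)
}

#' Cumulative tail-removal regression scan
#'
#' For each removal fraction `f`, drops individuals whose score lies
#' strictly above the empirical `1 - f` quantile and fits
#' `outcome ~ score + covariates` by least squares, recording the score
#' coefficient with its 95% CI, p-value and analysis `n`.  A rising
#' coefficient as the top tail is removed is the signature of a cliff-edge
#' penalty acting at high liability.
#'
#' @param score per-individual genetic score.
#' @param outcome per-individual outcome.
#' @param covariates data.frame of covariates (may have zero columns).
#' @param fractions removal fractions, ascending, in `[0, 0.5]`; 0 is the
#'   plain full-sample regression.
#' @param case_flag optional per-individual disorder indicator.
#' @param exclude_cases drop flagged cases before scanning.
#' @return a data.frame with columns `removal_fraction`, `beta`, `ci_low`,
#'   `ci_high`, `pval`, `n`.
#' @export
centile_removal_scan <- function(score, outcome, covariates = NULL,
                                 fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                                 case_flag = NULL, exclude_cases = FALSE) {
  stopifnot(!is.unsorted(fractions), all(fractions >= 0 & fractions <= 0.5))
  covmat <- if (is.null(covariates) || NCOL(covariates) == 0)
    matrix(nrow = length(score), ncol = 0) else as.matrix(covariates)
  keep <- !is.na(score) & !is.na(outcome) & stats::complete.cases(covmat)
  if (exclude_cases && !is.null(case_flag)) keep <- keep & case_flag == 0
  s <- score[keep]; y <- outcome[keep]
  covmat <- covmat[keep, , drop = FALSE]
  rows <- lapply(fractions, function(f) {
    inb <- if (f == 0) rep(TRUE, length(s)) else
      s <= stats::quantile(s, 1 - f, names = FALSE)
    if (!any(inb)) stop("empty retained set at fraction ", f)
    X <- cbind(1, score = s[inb], covmat[inb, , drop = FALSE])
    fit <- ols_fit(X, y[inb])
    b <- fit$coef[2]; se <- fit$se[2]
    data.frame(removal_fraction = f, beta = unname(b),
               ci_low = unname(b - 1.96 * se), ci_high = unname(b + 1.96 * se),
               pval = 2 * stats::pnorm(-abs(b / se)), n = fit$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

quadratic_fit_one <- function(s, y, covmat, group) {
  m <- mean(s)
  sc <- s - m  # centered for numerical conditioning
  X <- cbind(1, sc, sc2 = sc^2, covmat)
  fit <- tryCatch(ols_fit(X, y), error = function(e) NULL)
  if (is.null(fit))
    return(data.frame(group = group, linear_beta = NA_real_,
                      linear_ci_low = NA_real_, linear_ci_high = NA_real_,
                      linear_pval = NA_real_, quadratic_beta = NA_real_,
                      quadratic_ci_low = NA_real_,
                      quadratic_ci_high = NA_real_,
                      quadratic_pval = NA_real_, vertex_score = NA_real_,
                      n = sum(!is.na(y)), stringsAsFactors = FALSE))
  b1 <- fit$coef[2]; b2 <- fit$coef[3]
  # report on the raw-score scale via the polynomial identity
  # y = b1 (s - m) + b2 (s - m)^2  =  (b1 - 2 b2 m) s + b2 s^2 + const
  lin_raw <- b1 - 2 * b2 * m
  var_lin <- fit$vcov[2, 2] + 4 * m^2 * fit$vcov[3, 3] -
    4 * m * fit$vcov[2, 3]
  se_lin <- sqrt(var_lin)
  se_quad <- fit$se[3]
  vertex <- if (is.finite(b2) && b2 != 0) m - b1 / (2 * b2) else NA_real_
  data.frame(
    group = group,
    linear_beta = unname(lin_raw),
    linear_ci_low = unname(lin_raw - 1.96 * se_lin),
    linear_ci_high = unname(lin_raw + 1.96 * se_lin),
    linear_pval = 2 * stats::pnorm(-abs(lin_raw / se_lin)),
    quadratic_beta = unname(b2),
    quadratic_ci_low = unname(b2 - 1.96 * se_quad),
    quadratic_ci_high = unname(b2 + 1.96 * se_quad),
    quadratic_pval = 2 * stats::pnorm(-abs(b2 / se_quad)),
    vertex_score = unname(vertex), n = fit$n, stringsAsFactors = FALSE)
}

#' Quadratic regression of outcome on genetic score
#'
#' Fits `outcome ~ score + score^2 + covariates` (the score is mean-centered
#' before squaring for numerical conditioning; coefficients are reported on
#' the raw-score scale via the polynomial identity).  Reports both
#' coefficients with 95% CI and p, plus the stationary point
#' (`vertex_score = -b/(2a)` on the raw scale).  With `by_sex = TRUE`,
#' per-sex fits are added (the `sex` covariate column, if present, is
#' dropped within strata).
#'
#' @param score,outcome per-individual score and outcome.
#' @param covariates data.frame of covariates; a column named `sex` is used
#'   for stratification.
#' @param by_sex also fit females (`sex == 0`) and males (`sex == 1`)
#'   separately.
#' @return a data.frame with one row per group (`combined`, and optionally
#'   `female`/`male`).
#' @export
quadratic_fit <- function(score, outcome, covariates = NULL,
                          by_sex = FALSE) {
  covdf <- if (is.null(covariates)) data.frame(row.names = seq_along(score))
    else as.data.frame(covariates)
  covmat <- if (ncol(covdf)) as.matrix(covdf) else
    matrix(nrow = length(score), ncol = 0)
  keep <- !is.na(score) & !is.na(outcome) & stats::complete.cases(covmat)
  res <- quadratic_fit_one(score[keep], outcome[keep],
                           covmat[keep, , drop = FALSE], "combined")
  if (by_sex) {
    if (!"sex" %in% names(covdf))
      stop("by_sex = TRUE requires a 'sex' covariate column")
    sex <- covdf$sex
    strat_cov <- covmat[, setdiff(colnames(covmat), "sex"), drop = FALSE]
    for (grp in c("female", "male")) {
      code <- if (grp == "female") 0 else 1
      i <- keep & sex == code
      res <- rbind(res, quadratic_fit_one(score[i], outcome[i],
                                          strat_cov[i, , drop = FALSE], grp))
    }
  }
  rownames(res) <- NULL
  res
}
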