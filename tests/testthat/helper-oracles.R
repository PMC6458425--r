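# Independent oracles, kept deliberately naive and separate from the
# package's estimator code paths.

# zero-intercept weighted least squares via explicit normal equations
wls_zero_intercept_oracle <- function(bx, by, w) {
  sum(w * bx * by) / sum(w * bx^2)
}

# weighted least squares with free intercept via explicit normal equations
# (matrix inversion with diag(w), nothing shared with the package)
wls_intercept_oracle <- function(bx, by, w) {
  X <- cbind(1, bx)
  coefs <- solve(t(X) %*% diag(w) %*% X) %*% (t(X) %*% diag(w) %*% by)
  c(intercept = coefs[1], slope = coefs[2])
}

# cumulative-weight interpolated weighted median, written as a plain loop
weighted_median_oracle <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- numeric(length(w))
  acc <- 0
  for (i in seq_along(w)) {
    p[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  for (i in seq_len(length(p) - 1)) {
    if (p[i] <= 0.5 && 0.5 <= p[i + 1]) {
      return(r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("unreachable")
}

# plain normal-equations OLS: coefficients and SEs
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  coefs <- XtX_inv %*% (t(X) %*% y)
  res <- y - X %*% coefs
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = as.vector(coefs), se = sqrt(diag(XtX_inv) * sigma2))
}

# a random small instrument set for oracle-equivalence checks
random_instruments <- function(k, seed) {
  set.seed(seed)
  data.frame(
    snp = paste0("rs", seq_len(k)),
    beta_exp = abs(rnorm(k, 0.1, 0.05)) + 0.01,
    se_exp = runif(k, 0.005, 0.03),
    beta_out = rnorm(k, 0.05, 0.05),
    se_out = runif(k, 0.005, 0.03),
    stringsAsFactors = FALSE)
}

# a hand-built cohort_table, bypassing the generator
make_tiny_cohort <- function(dosages, counted, other, risk,
                             phenotypes) {
  structure(list(
    dosages = dosages,
    snp_info = data.frame(snp = colnames(dosages), counted_allele = counted,
                          other_allele = other, maf = colMeans(dosages,
                                                              na.rm = TRUE) / 2,
                          risk_allele = risk, stringsAsFactors = FALSE),
    phenotypes = phenotypes), class = "cohort_table")
}

# expected mean of round(pmax(0, N(mu, sd))): the count-phenotype
# truncation/rounding map, evaluated by direct summation
expected_rounded_truncated_normal <- function(mu, sd, kmax = 60) {
  k <- seq_len(kmax)
  sum(k * (pnorm((k + 0.5 - mu) / sd) - pnorm((k - 0.5 - mu) / sd)))
}
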