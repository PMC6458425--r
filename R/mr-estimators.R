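# Two-sample MR estimators and instrument diagnostics.
#
# All estimators consume a "harmonized_instruments" data.frame (see
# harmonize()) whose instruments are oriented to the exposure-increasing
# allele.  Confidence intervals use the normal 1.96 multiplier on the
# estimation scale; random-effects standard errors use multiplicative
# overdispersion, inflating the fixed-effect SE by sqrt(Q/df) floored at 1.

CI_Z <- 1.96
LOG2 <- 0.693  # per-doubling-of-odds factor, fixed at the conventional 3 d.p.

new_mr_estimate <- function(method, beta, se, n_snps, scale = "raw",
                            diagnostics = NULL) {
  pval <- if (is.na(se) || se == 0) NA_real_ else
    2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
                 pval = pval, n_snps = n_snps, scale = scale,
                 diagnostics = diagnostics),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s, scale=%s]: beta = %.4g (95%% CI %.4g to %.4g), se = %.4g, p = %.3g, k = %d\n",
              x$method, x$scale, x$beta, x$ci_low, x$ci_high, x$se,
              x$pval, x$n_snps))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pval = x$pval, n_snps = x$n_snps,
             scale = x$scale, stringsAsFactors = FALSE)
}

check_instruments <- function(instruments, k_min = 1L) {
  stopifnot(is.data.frame(instruments),
            all(c("beta_exp", "se_exp", "beta_out", "se_out") %in%
                  names(instruments)))
  if (nrow(instruments) < k_min)
    stop("at least ", k_min, " instrument(s) required, got ",
         nrow(instruments))
  invisible(instruments)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with the first-order delta-method standard error
#' `se_out / beta_exp`.
#'
#' @param inst a one-row harmonized-instruments data.frame.
#' @return an `"mr_estimate"`.
#' @export
wald_ratio <- function(inst) {
  check_instruments(inst, 1L)
  inst <- inst[1L, ]
  if (inst$beta_exp == 0) stop("undefined ratio: beta_exp is zero")
  new_mr_estimate("wald", inst$beta_out / inst$beta_exp,
                  inst$se_out / abs(inst$beta_exp), 1L)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Equivalent to a weighted regression of SNP-outcome on SNP-exposure
#' coefficients with the intercept constrained to zero, weights
#' `1/se_out^2`:
#' `beta = sum(w b_out b_exp) / sum(w b_exp^2)`.  The fixed-effect SE is
#' `1/sqrt(sum(w b_exp^2))`; with `k >= 2` instruments a multiplicative
#' random-effects SE inflates it by `max(1, sqrt(Q/(k-1)))` where Cochran's
#' `Q = sum w (b_out - beta b_exp)^2` measures overdispersion.
#'
#' @param instruments a harmonized-instruments data.frame.
#' @param random_effects use the multiplicative random-effects SE (default);
#'   otherwise fixed-effect.
#' @return an `"mr_estimate"` whose `diagnostics` hold `cochran_q` and
#'   `q_df` (absent for a single instrument, where IVW reduces exactly to
#'   the Wald ratio).
#' @export
mr_ivw <- function(instruments, random_effects = TRUE) {
  check_instruments(instruments, 1L)
  k <- nrow(instruments)
  w <- 1 / instruments$se_out^2
  bx <- instruments$beta_exp
  by <- instruments$beta_out
  denom <- sum(w * bx^2)
  if (denom == 0) stop("all exposure effects are zero")
  beta <- sum(w * by * bx) / denom
  se_fixed <- 1 / sqrt(denom)
  if (k >= 2) {
    q <- sum(w * (by - beta * bx)^2)
    se <- if (random_effects) se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
    diag <- list(cochran_q = q, q_df = k - 1L)
  } else {
    se <- se_fixed
    diag <- list(cochran_q = NA_real_, q_df = NA_integer_)
  }
  new_mr_estimate("ivw", beta, se, k, diagnostics = diag)
}

# weighted least squares with intercept via normal equations
wls_with_intercept <- function(bx, by, w) {
  X <- cbind(1, bx)
  A <- crossprod(X, w * X)
  coefs <- tryCatch(solve(A, crossprod(X, w * by)),
                    error = function(e)
                      stop("collinearity error: no spread in beta_exp"))
  fitted <- X %*% coefs
  list(intercept = coefs[1], slope = coefs[2],
       cov_fixed = solve(A), resid = by - as.vector(fitted))
}

#' MR-Egger regression
#'
#' Weighted least squares of SNP-outcome on SNP-exposure coefficients with a
#' free intercept (weights `1/se_out^2`), fitted on instruments oriented to
#' the exposure-increasing allele.  The intercept estimates average
#' directional pleiotropy; the slope is the causal estimate under the InSIDE
#' assumption.  Both SEs use multiplicative random-effects inflation with
#' `df = k - 2`.
#'
#' @param instruments a harmonized-instruments data.frame with `k >= 2`
#'   (`k >= 3` recommended).
#' @return a list with `"mr_estimate"` elements `slope` and `intercept`.
#' @export
mr_egger <- function(instruments) {
  check_instruments(instruments, 2L)
  k <- nrow(instruments)
  w <- 1 / instruments$se_out^2
  fit <- wls_with_intercept(instruments$beta_exp, instruments$beta_out, w)
  q <- sum(w * fit$resid^2)
  infl <- if (k > 2) max(1, sqrt(q / (k - 2))) else 1
  se <- sqrt(diag(fit$cov_fixed)) * infl
  diag <- list(cochran_q = q, q_df = k - 2L)
  list(slope = new_mr_estimate("egger_slope", fit$slope, se[2], k,
                               diagnostics = diag),
       intercept = new_mr_estimate("egger_intercept", fit$intercept, se[1],
                                   k, diagnostics = diag))
}

# interpolated weighted median of ratio estimates (shared by point estimate
# and bootstrap)
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  i <- findInterval(0.5, p)
  r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

#' Weighted median estimator
#'
#' The inverse-variance weighted median of the per-SNP ratio estimates:
#' ratio estimates are sorted and the estimate is the value at which the
#' normalized cumulative weight crosses one half, linearly interpolated
#' between the bracketing ratios at their cumulative-weight midpoints.
#' Consistent when at least half of the total weight comes from valid
#' instruments.  The standard error comes from a seeded parametric
#' bootstrap: exposure and outcome effects are redrawn from
#' `N(beta, se)`, the estimator recomputed, and the SD over `n_boot`
#' draws taken.
#'
#' @param instruments a harmonized-instruments data.frame with `k >= 3`.
#' @param n_boot bootstrap draws for the SE (0 skips the bootstrap and
#'   returns `NA` SE).
#' @param seed seed for the bootstrap stream.
#' @return an `"mr_estimate"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  check_instruments(instruments, 3L)
  k <- nrow(instruments)
  bx <- instruments$beta_exp; by <- instruments$beta_out
  sx <- instruments$se_exp; sy <- instruments$se_out
  w <- bx^2 / sy^2
  if (all(w == 0)) stop("all weights are zero")
  beta <- weighted_median_point(by / bx, w)
  se <- NA_real_
  if (n_boot > 0) {
    seed_stage(seed, "weighted_median_boot")
    bxs <- matrix(stats::rnorm(k * n_boot, bx, sx), nrow = k)
    bys <- matrix(stats::rnorm(k * n_boot, by, sy), nrow = k)
    draws <- vapply(seq_len(n_boot), function(b) {
      weighted_median_point(bys[, b] / bxs[, b], bxs[, b]^2 / sy^2)
    }, numeric(1))
    se <- stats::sd(draws)
  }
  new_mr_estimate("weighted_median", beta, se, k)
}

# kernel-density mode of the ratio estimates; bandwidth = phi x modified
# Silverman rule on a MAD-robust scale; argmax on a fixed grid with ties
# broken toward the smallest grid value (which.max returns the first).
mode_point <- function(ratios, weights, phi, n_grid = 10000L) {
  s <- min(stats::sd(ratios), stats::mad(ratios))
  if (!is.finite(s) || s <= 0) return(list(beta = ratios[1], degenerate = TRUE))
  h <- phi * 0.9 * s * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = n_grid)
  z <- outer(grid, ratios, "-") / h
  dens <- as.vector(exp(-0.5 * z^2) %*% (weights / sum(weights)))
  list(beta = grid[which.max(dens)], degenerate = FALSE)
}

#' Mode-based estimator
#'
#' The mode of the normal-kernel-smoothed distribution of per-SNP ratio
#' estimates, consistent when the largest cluster of similar instrument
#' estimates comes from valid instruments.  Bandwidth is
#' `phi x h_silverman`, where `h_silverman = 0.9 min(sd, mad) k^(-1/5)` over
#' the ratio set; the argmax is located on a 10 000-point grid spanning the
#' ratio range padded by three bandwidths (ties break toward the smallest
#' grid value).  The simple mode uses equal kernel weights; the weighted
#' mode weights each kernel by `beta_exp^2/se_out^2`.  If all ratios
#' coincide, the common ratio is returned with zero SE, flagged degenerate.
#'
#' @param instruments a harmonized-instruments data.frame with `k >= 3`.
#' @param weighted use inverse-variance kernel weights.
#' @param phi bandwidth tuning parameter (default 0.5).
#' @param n_boot parametric-bootstrap draws for the SE (0 skips).
#' @param seed seed for the bootstrap stream.
#' @return an `"mr_estimate"`; degenerate inputs are flagged in
#'   `diagnostics$degenerate`.
#' @export
mr_mode <- function(instruments, weighted = FALSE, phi = 0.5,
                    n_boot = 1000L, seed = 1L) {
  check_instruments(instruments, 3L)
  stopifnot(phi > 0)
  k <- nrow(instruments)
  bx <- instruments$beta_exp; by <- instruments$beta_out
  sx <- instruments$se_exp; sy <- instruments$se_out
  wts <- function(bx_) if (weighted) bx_^2 / sy^2 else rep(1, k)
  pt <- mode_point(by / bx, wts(bx), phi)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  if (pt$degenerate)
    return(new_mr_estimate(method, pt$beta, 0, k,
                           diagnostics = list(degenerate = TRUE)))
  se <- NA_real_
  if (n_boot > 0) {
    seed_stage(seed, paste0(method, "_boot"))
    bxs <- matrix(stats::rnorm(k * n_boot, bx, sx), nrow = k)
    bys <- matrix(stats::rnorm(k * n_boot, by, sy), nrow = k)
    draws <- vapply(seq_len(n_boot), function(b) {
      mode_point(bys[, b] / bxs[, b], wts(bxs[, b]), phi)$beta
    }, numeric(1))
    se <- stats::sd(draws)
  }
  new_mr_estimate(method, pt$beta, se, k,
                  diagnostics = list(degenerate = FALSE))
}

#' Mean F-statistic (instrument strength)
#'
#' The mean over instruments of the squared SNP-exposure effect divided by
#' its squared standard error.  Values above 10 conventionally indicate
#' acceptable instrument strength.
#'
#' @param instruments a harmonized-instruments data.frame.
#' @return a single number.
#' @export
mean_f_statistic <- function(instruments) {
  check_instruments(instruments, 1L)
  mean(instruments$beta_exp^2 / instruments$se_exp^2)
}

#' I-squared GX statistic (MR-Egger suitability)
#'
#' Quantifies relative dilution of the MR-Egger slope from measurement error
#' in the SNP-exposure estimates; values above 0.9 are desired.  The
#' weighted variant uses `Q_GX = sum (b_exp - b_ivw_mean)^2 / se_exp^2` with
#' the inverse-variance-weighted mean of `beta_exp`; the unweighted variant
#' uses the unweighted mean with unit weights scaled by the mean squared SE,
#' `Q_GX = sum (b_exp - mean(b_exp))^2 / mean(se_exp^2)`.  In both cases
#' `I2_GX = max(0, (Q_GX - (k-1)) / Q_GX)`.
#'
#' @param instruments a harmonized-instruments data.frame with `k >= 2`.
#' @param weighted use the inverse-variance-weighted variant.
#' @return a number in `[0, 1]`.
#' @export
i2_gx <- function(instruments, weighted = FALSE) {
  check_instruments(instruments, 2L)
  bx <- instruments$beta_exp
  sx2 <- instruments$se_exp^2
  k <- length(bx)
  q <- if (weighted) {
    centre <- sum(bx / sx2) / sum(1 / sx2)
    sum((bx - centre)^2 / sx2)
  } else {
    sum((bx - mean(bx))^2 / mean(sx2))
  }
  if (q == 0) return(0)
  max(0, (q - (k - 1)) / q)
}

#' Rescale a binary-exposure estimate to per-doubling-of-odds units
#'
#' Multiplies the estimate, its SE and its CI bounds by 0.693 so a
#' log-odds-scale binary-liability exposure is expressed per doubling in the
#' odds of the exposure.  The p-value is unchanged.  Guarded against double
#' application via the `scale` field.
#'
#' @param est an `"mr_estimate"` on the raw scale.
#' @return the rescaled `"mr_estimate"` (`scale = "per_doubling_odds"`).
#' @export
scale_binary_exposure <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  if (est$scale != "raw")
    stop("scale guard: estimate is already on scale '", est$scale, "'")
  est$beta <- est$beta * LOG2
  est$se <- est$se * LOG2
  est$ci_low <- est$ci_low * LOG2
  est$ci_high <- est$ci_high * LOG2
  est$scale <- "per_doubling_odds"
  est
}

#' Convert a log-odds-scale estimate to an odds ratio
#'
#' For binary outcomes: exponentiates the estimate and its CI bounds.  With
#' `binary_exposure = TRUE` a raw estimate is first put on the
#' per-doubling-of-odds scale (x 0.693), so the result is the OR per
#' doubling in the odds of the exposure.  The SE stays on the log scale and
#' the p-value is unchanged.
#'
#' @param est an `"mr_estimate"` on the raw or per-doubling-of-odds scale,
#'   whose outcome effect is a log odds ratio.
#' @param binary_exposure apply the 0.693 doubling factor first (only valid
#'   from the raw scale).
#' @return the converted `"mr_estimate"` (`scale = "odds_ratio"`).
#' @export
to_odds_ratio <- function(est, binary_exposure = FALSE) {
  stopifnot(inherits(est, "mr_estimate"))
  if (est$scale == "odds_ratio")
    stop("scale guard: estimate is already an odds ratio")
  if (binary_exposure) {
    if (est$scale != "raw")
      stop("scale guard: doubling factor requires a raw-scale estimate")
    est <- scale_binary_exposure(est)
  }
  est$beta <- exp(est$beta)
  est$ci_low <- exp(est$ci_low)
  est$ci_high <- exp(est$ci_high)
  est$scale <- "odds_ratio"
  est
}

#' Run the full MR estimator suite on one exposure-outcome pair
#'
#' Harmonizes the two summary-statistics tables, computes IVW, MR-Egger
#' (slope and intercept), weighted median, and simple and weighted
#' mode-based estimates with instrument diagnostics (Cochran's Q, mean F,
#' I2GX), and applies the scale conventions: binary-liability exposures are
#' rescaled per doubling of odds (x 0.693) and binary outcomes are
#' exponentiated to odds ratios.  The MR-Egger intercept, which measures
#' pleiotropy per SNP rather than per unit exposure, is never rescaled by
#' 0.693 (it is exponentiated for binary outcomes).
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param binary_exposure exposure is a binary-disease liability on the
#'   log-odds scale.
#' @param binary_outcome outcome effects are log odds ratios.
#' @param palindromic_policy passed to [harmonize()].
#' @param phi mode-estimator bandwidth tuning parameter.
#' @param n_boot bootstrap draws for median/mode SEs.
#' @param seed seed for bootstrap streams.
#' @return a data.frame with one row per method (`ivw`, `egger_intercept`,
#'   `egger_slope`, `weighted_median`, `simple_mode`, `weighted_mode`) and
#'   columns `beta`, `se`, `ci_low`, `ci_high`, `pval`, `n_snps`, `scale`,
#'   `cochran_q`, `q_df`, `mean_f`, `i2_gx`, `i2_gx_weighted`.  The
#'   harmonized instruments are attached as the `"instruments"` attribute.
#' @examples
#' ss <- gen_two_sample_summary(sim_config(n_snps = 30,
#'                                         true_causal_effect = 0.1))
#' run_mr_suite(ss$exposure, ss$outcome, n_boot = 100)
#' @export
run_mr_suite <- function(exposure, outcome, binary_exposure = FALSE,
                         binary_outcome = FALSE,
                         palindromic_policy = "infer_by_eaf", phi = 0.5,
                         n_boot = 1000L, seed = 1L) {
  inst <- harmonize(exposure, outcome, palindromic_policy)
  if (nrow(inst) < 3)
    stop("stage mr_suite: fewer than 3 instruments after harmonization")
  ivw <- mr_ivw(inst)
  egger <- mr_egger(inst)
  wmed <- mr_weighted_median(inst, n_boot = n_boot, seed = seed)
  smode <- mr_mode(inst, weighted = FALSE, phi = phi, n_boot = n_boot,
                   seed = seed)
  wmode <- mr_mode(inst, weighted = TRUE, phi = phi, n_boot = n_boot,
                   seed = seed)

  rescale <- function(est, is_slope) {
    if (binary_exposure && is_slope && !binary_outcome)
      est <- scale_binary_exposure(est)
    if (binary_outcome)
      est <- to_odds_ratio(est, binary_exposure = binary_exposure && is_slope)
    est
  }
  ests <- list(rescale(ivw, TRUE),
               rescale(egger$intercept, FALSE),
               rescale(egger$slope, TRUE),
               rescale(wmed, TRUE),
               rescale(smode, TRUE),
               rescale(wmode, TRUE))
  tab <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(tab) <- NULL
  tab$cochran_q <- ivw$diagnostics$cochran_q
  tab$q_df <- ivw$diagnostics$q_df
  tab$mean_f <- mean_f_statistic(inst)
  tab$i2_gx <- i2_gx(inst, weighted = FALSE)
  tab$i2_gx_weighted <- i2_gx(inst, weighted = TRUE)
  attr(tab, "instruments") <- inst
  tab
}
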