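# Simplified LD score regression: ordinary least squares of (cross-)chi-square
# statistics on LD scores, with block-jackknife standard errors.  No
# iterative heteroskedasticity weighting and no reference LD files are used;
# panels come from gen_ldsc_panel() or a TSV with columns snp, l2, z1, z2,
# n1, n2.

# contiguous block assignment for the jackknife
jackknife_blocks <- function(M, n_blocks) {
  n_blocks <- min(n_blocks, M)
  sizes <- diff(round(seq(0, M, length.out = n_blocks + 1)))
  rep(seq_len(n_blocks), times = sizes)
}

# simple-regression slope/intercept from sufficient statistics, plus
# per-block sums enabling delete-one-block recomputation
block_ols <- function(x, y, blocks) {
  n_blocks <- max(blocks)
  sums <- function(v) vapply(split(v, blocks), sum, numeric(1))
  bs <- list(n = tabulate(blocks, n_blocks), sx = sums(x), sy = sums(y),
             sxx = sums(x * x), sxy = sums(x * y))
  tot <- lapply(bs, sum)
  est <- function(n, sx, sy, sxx, sxy) {
    vx <- sxx - sx^2 / n
    slope <- (sxy - sx * sy / n) / vx
    c(slope = slope, intercept = sy / n - slope * sx / n)
  }
  full <- est(tot$n, tot$sx, tot$sy, tot$sxx, tot$sxy)
  loo <- vapply(seq_len(n_blocks), function(b) {
    est(tot$n - bs$n[b], tot$sx - bs$sx[b], tot$sy - bs$sy[b],
        tot$sxx - bs$sxx[b], tot$sxy - bs$sxy[b])
  }, c(slope = 0, intercept = 0))
  list(full = full, loo = t(loo), n_blocks = n_blocks)
}

jackknife_se <- function(theta_loo) {
  B <- length(theta_loo)
  sqrt((B - 1) / B * sum((theta_loo - mean(theta_loo))^2))
}

read_panel <- function(panel) {
  if (is.character(panel)) {
    panel <- utils::read.delim(panel, stringsAsFactors = FALSE)
    attr(panel, "M") <- nrow(panel)
  }
  stopifnot(all(c("l2", "z1", "z2", "n1", "n2") %in% names(panel)))
  if (any(panel$l2 <= 0)) stop("LD scores must be positive")
  panel
}

#' Univariate LD score regression
#'
#' Regresses squared z-scores on LD scores by OLS:
#' `E[z^2] = intercept + N h2 l_j / M`, so the heritability estimate is
#' `slope * M / N`.  Standard errors come from a delete-one block jackknife
#' over contiguous blocks.  A negative fitted slope is reported as is (no
#' truncation, keeping the estimator's unbiasedness testable) and flagged.
#'
#' @param panel an `"ldsc_panel"` data.frame (or path to one as TSV).
#' @param trait 1 or 2: which trait's z-scores to use.
#' @param n_blocks jackknife blocks (default 200).
#' @return a list with `h2`, `h2_se`, `intercept`, `intercept_se`, `M`,
#'   `N`, and `negative_slope` flag.
#' @export
univariate_ldsc <- function(panel, trait = 1, n_blocks = 200L) {
  panel <- read_panel(panel)
  M <- attr(panel, "M")
  if (is.null(M)) M <- nrow(panel)
  if (M < 200) stop("at least 200 SNPs required for stable fitting")
  z <- if (trait == 1) panel$z1 else panel$z2
  N <- as.numeric(if (trait == 1) panel$n1[1] else panel$n2[1])
  blocks <- jackknife_blocks(M, n_blocks)
  ols <- block_ols(panel$l2, z^2, blocks)
  h2 <- unname(ols$full["slope"]) * M / N
  list(h2 = h2,
       h2_se = jackknife_se(ols$loo[, "slope"] * M / N),
       intercept = unname(ols$full["intercept"]),
       intercept_se = jackknife_se(ols$loo[, "intercept"]),
       M = M, N = N, negative_slope = h2 < 0)
}

#' Cross-trait LD score regression (genetic correlation)
#'
#' Regresses `z1 * z2` on LD scores: the genetic covariance is
#' `rho_g = slope * M / sqrt(N1 N2)` and the genetic correlation is
#' `rg = rho_g / sqrt(h2_1 h2_2)` with the univariate heritabilities from
#' [univariate_ldsc()] on the same panel.  The intercept estimates
#' sample-overlap confounding.  The jackknife recomputes the full pipeline
#' (both heritabilities and the covariance) per deleted block, so the rg SE
#' propagates all three regressions.  Noisy `|rg|` may exceed 1; it is
#' flagged but not truncated.
#'
#' @param panel an `"ldsc_panel"` data.frame (or TSV path).
#' @param n_blocks jackknife blocks (default 200).
#' @return a list with `rg`, `rg_se`, `pval` (normal test of rg = 0),
#'   `rho_g`, `rho_g_se`, `intercept`, `intercept_se`, `h2_1`, `h2_2`, `M`,
#'   and `rg_out_of_range` flag.
#' @export
cross_trait_ldsc <- function(panel, n_blocks = 200L) {
  panel <- read_panel(panel)
  M <- attr(panel, "M")
  if (is.null(M)) M <- nrow(panel)
  if (M < 200) stop("at least 200 SNPs required for stable fitting")
  N1 <- as.numeric(panel$n1[1]); N2 <- as.numeric(panel$n2[1])
  blocks <- jackknife_blocks(M, n_blocks)
  o1 <- block_ols(panel$l2, panel$z1^2, blocks)
  o2 <- block_ols(panel$l2, panel$z2^2, blocks)
  o12 <- block_ols(panel$l2, panel$z1 * panel$z2, blocks)
  h2_1 <- unname(o1$full["slope"]) * M / N1
  h2_2 <- unname(o2$full["slope"]) * M / N2
  if (h2_1 <= 0 || h2_2 <= 0)
    stop("rg undefined: non-positive heritability estimate for trait ",
         if (h2_1 <= 0) "1" else "2")
  rho_g <- unname(o12$full["slope"]) * M / sqrt(N1 * N2)
  rg <- rho_g / sqrt(h2_1 * h2_2)
  loo_rho <- o12$loo[, "slope"] * M / sqrt(N1 * N2)
  loo_h1 <- o1$loo[, "slope"] * M / N1
  loo_h2 <- o2$loo[, "slope"] * M / N2
  ok <- loo_h1 > 0 & loo_h2 > 0
  loo_rg <- loo_rho[ok] / sqrt(loo_h1[ok] * loo_h2[ok])
  rg_se <- jackknife_se(loo_rg)
  list(rg = rg, rg_se = rg_se,
       pval = 2 * stats::pnorm(-abs(rg / rg_se)),
       rho_g = rho_g, rho_g_se = jackknife_se(loo_rho),
       intercept = unname(o12$full["intercept"]),
       intercept_se = jackknife_se(o12$loo[, "intercept"]),
       h2_1 = h2_1, h2_2 = h2_2, M = M,
       rg_out_of_range = abs(rg) > 1)
}
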