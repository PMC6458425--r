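# Unit and property tests for the MR estimator suite.

test_that("Wald ratio follows the delta method and IVW reduces to it for k = 1", {
  inst <- data.frame(snp = "rs1", beta_exp = 0.10, se_exp = 0.02,
                     beta_out = 0.05, se_out = 0.01)
  w <- wald_ratio(inst)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  ivw <- mr_ivw(inst)
  expect_equal(ivw$beta, w$beta)
  expect_equal(ivw$se, w$se)
  expect_true(is.na(ivw$diagnostics$cochran_q))
  bad <- inst; bad$beta_exp <- 0
  expect_error(wald_ratio(bad), "undefined ratio")
})

test_that("IVW equals the zero-intercept WLS oracle and Q vanishes without heterogeneity", {
  inst <- data.frame(snp = paste0("rs", 1:3),
                     beta_exp = c(0.1, 0.2, 0.15), se_exp = 0.01,
                     beta_out = c(0.05, 0.09, 0.08),
                     se_out = c(0.01, 0.01, 0.02))
  est <- mr_ivw(inst)
  oracle <- wls_zero_intercept_oracle(inst$beta_exp, inst$beta_out,
                                      1 / inst$se_out^2)
  expect_equal(est$beta, oracle, tolerance = 1e-10)

  # two instruments with identical Wald ratios: beta is that ratio, Q = 0
  same <- data.frame(snp = c("a", "b"), beta_exp = c(0.1, 0.2),
                     se_exp = 0.01, beta_out = c(0.05, 0.10),
                     se_out = c(0.01, 0.02))
  est2 <- mr_ivw(same)
  expect_equal(est2$beta, 0.5, tolerance = 1e-12)
  expect_equal(est2$diagnostics$cochran_q, 0, tolerance = 1e-20)
  expect_error(mr_ivw(inst[0, ]), "at least 1")
})

test_that("MR-Egger interpolates two points exactly and matches the WLS oracle", {
  two <- data.frame(snp = c("a", "b"), beta_exp = c(0.1, 0.3),
                    se_exp = 0.01, beta_out = c(0.02, 0.09),
                    se_out = c(0.01, 0.02))
  fit <- mr_egger(two)
  expect_equal(fit$intercept$beta + fit$slope$beta * two$beta_exp,
               two$beta_out, tolerance = 1e-12)

  inst <- random_instruments(8, seed = 42)
  fit <- mr_egger(inst)
  oracle <- wls_intercept_oracle(inst$beta_exp, inst$beta_out,
                                 1 / inst$se_out^2)
  expect_equal(fit$slope$beta, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept$beta, unname(oracle["intercept"]),
               tolerance = 1e-10)
  # intercept = weighted mean of beta_out minus slope x weighted mean of beta_exp
  w <- 1 / inst$se_out^2
  expect_equal(fit$intercept$beta,
               weighted.mean(inst$beta_out, w) -
                 fit$slope$beta * weighted.mean(inst$beta_exp, w),
               tolerance = 1e-10)
  degenerate <- data.frame(snp = c("a", "b"), beta_exp = c(0.1, 0.1),
                           se_exp = 0.01, beta_out = c(0.1, 0.2),
                           se_out = 0.01)
  expect_error(mr_egger(degenerate), "collinearity")
})

test_that("weighted median interpolates the cumulative-weight midpoint scale", {
  # equal weights, ratios {1,2,3,4,10}: cumulative weight crosses 0.5 at the
  # middle ratio
  inst <- data.frame(snp = paste0("rs", 1:5), beta_exp = 1, se_exp = 0.01,
                     beta_out = c(1, 2, 3, 4, 10), se_out = 1)
  expect_equal(mr_weighted_median(inst, n_boot = 0)$beta, 3)

  # all ratios equal r: beta = r whatever the weights
  inst2 <- data.frame(snp = paste0("rs", 1:4),
                      beta_exp = c(0.1, 0.2, 0.4, 0.5), se_exp = 0.01,
                      beta_out = c(0.1, 0.2, 0.4, 0.5) * 0.7,
                      se_out = c(0.01, 0.03, 0.02, 0.05))
  expect_equal(mr_weighted_median(inst2, n_boot = 0)$beta, 0.7,
               tolerance = 1e-12)

  # random sets match the loop-written oracle and stay inside the ratio range
  for (s in 1:25) {
    inst <- random_instruments(sample(3:12, 1), seed = 1000 + s)
    est <- mr_weighted_median(inst, n_boot = 0)$beta
    ratios <- inst$beta_out / inst$beta_exp
    expect_equal(est, weighted_median_oracle(ratios,
                                             inst$beta_exp^2 / inst$se_out^2),
                 tolerance = 1e-12)
    expect_gte(est, min(ratios))
    expect_lte(est, max(ratios))
  }
})

test_that("weighted median resists an outlier better than IVW", {
  base <- data.frame(snp = paste0("rs", 1:8),
                     beta_exp = rep(0.2, 8), se_exp = 0.01,
                     beta_out = rep(0.1, 8), se_out = 0.01)
  outlier <- rbind(base, data.frame(snp = "rs9", beta_exp = 0.2,
                                    se_exp = 0.01, beta_out = 0.6,
                                    se_out = 0.05))
  shift_med <- abs(mr_weighted_median(outlier, n_boot = 0)$beta -
                     mr_weighted_median(base, n_boot = 0)$beta)
  shift_ivw <- abs(mr_ivw(outlier)$beta - mr_ivw(base)$beta)
  expect_lt(shift_med, shift_ivw)
})

test_that("mode-based estimator finds the majority cluster", {
  # 7 ratios near 0.1 and 3 near 0.9: simple mode lands near 0.1
  set.seed(11)
  ratios <- c(rnorm(7, 0.1, 0.01), rnorm(3, 0.9, 0.01))
  inst <- data.frame(snp = paste0("rs", 1:10), beta_exp = 1, se_exp = 0.01,
                     beta_out = ratios, se_out = 0.05)
  est <- mr_mode(inst, weighted = FALSE, n_boot = 0)
  expect_lt(abs(est$beta - 0.1), 0.05)

  # weighted and simple mode coincide when all weights are equal
  w_est <- mr_mode(inst, weighted = TRUE, n_boot = 0)
  expect_equal(w_est$beta, est$beta, tolerance = 1e-12)

  # all ratios identical: degenerate, beta = common ratio, se = 0
  deg <- data.frame(snp = paste0("rs", 1:3), beta_exp = c(0.1, 0.2, 0.4),
                    se_exp = 0.01, beta_out = c(0.05, 0.10, 0.20),
                    se_out = 0.01)
  dest <- mr_mode(deg, n_boot = 100)
  expect_equal(dest$beta, 0.5, tolerance = 1e-12)
  expect_equal(dest$se, 0)
  expect_true(dest$diagnostics$degenerate)
})

test_that("instrument diagnostics behave at their fixed points", {
  inst <- data.frame(snp = paste0("rs", 1:4), beta_exp = 0.02,
                     se_exp = 0.02, beta_out = 0.01, se_out = 0.01)
  expect_equal(mean_f_statistic(inst), 1.0)
  # no dispersion in beta_exp: Q_GX = 0 and I2GX truncates to 0
  expect_equal(i2_gx(inst, weighted = FALSE), 0)
  expect_equal(i2_gx(inst, weighted = TRUE), 0)
  inst2 <- random_instruments(20, seed = 7)
  for (wt in c(TRUE, FALSE)) {
    v <- i2_gx(inst2, weighted = wt)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(i2_gx(inst2[1, ]), "at least 2")
})

test_that("binary-exposure scaling and OR conversion follow the doubling convention", {
  inst <- random_instruments(10, seed = 3)
  est <- mr_ivw(inst)
  scaled <- scale_binary_exposure(est)
  expect_equal(scaled$beta, est$beta * 0.693)
  expect_equal(scaled$se, est$se * 0.693)
  expect_equal(scaled$ci_low, est$ci_low * 0.693)
  expect_equal(scaled$pval, est$pval)   # p unchanged
  expect_equal(scaled$beta / 0.693, est$beta, tolerance = 1e-12)
  expect_error(scale_binary_exposure(scaled), "scale guard")

  # null estimate is a fixed point
  null_est <- mr_ivw(data.frame(snp = "a", beta_exp = 0.1, se_exp = 0.01,
                                beta_out = 0, se_out = 0.01))
  expect_equal(scale_binary_exposure(null_est)$beta, 0)

  or <- to_odds_ratio(est, binary_exposure = TRUE)
  expect_equal(or$beta, exp(0.693 * est$beta))
  expect_lt(or$ci_low, or$beta); expect_gt(or$ci_high, or$beta)
  expect_error(to_odds_ratio(or), "scale guard")
  # log-OR 0 maps to OR 1
  expect_equal(to_odds_ratio(null_est)$beta, 1)
})

test_that("all estimators are scale-equivariant in the outcome", {
  inst <- random_instruments(12, seed = 5)
  scaled <- inst
  cc <- 3.7
  scaled$beta_out <- inst$beta_out * cc
  scaled$se_out <- inst$se_out * cc
  pairs <- list(
    c(mr_ivw(inst)$beta, mr_ivw(scaled)$beta),
    c(mr_ivw(inst)$se, mr_ivw(scaled)$se),
    c(mr_egger(inst)$slope$beta, mr_egger(scaled)$slope$beta),
    c(mr_egger(inst)$slope$se, mr_egger(scaled)$slope$se),
    c(mr_weighted_median(inst, n_boot = 0)$beta,
      mr_weighted_median(scaled, n_boot = 0)$beta),
    c(mr_mode(inst, n_boot = 0)$beta, mr_mode(scaled, n_boot = 0)$beta),
    c(mr_mode(inst, weighted = TRUE, n_boot = 0)$beta,
      mr_mode(scaled, weighted = TRUE, n_boot = 0)$beta))
  for (p in pairs) expect_equal(p[1] * cc, p[2], tolerance = 1e-8)
})

test_that("random-effects SEs never undercut fixed-effect SEs", {
  for (s in 1:10) {
    inst <- random_instruments(sample(3:15, 1), seed = 200 + s)
    expect_gte(mr_ivw(inst, random_effects = TRUE)$se,
               mr_ivw(inst, random_effects = FALSE)$se)
  }
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  inst <- random_instruments(8, seed = 9)
  a <- mr_weighted_median(inst, n_boot = 200, seed = 77)
  b <- mr_weighted_median(inst, n_boot = 200, seed = 77)
  expect_identical(a$se, b$se)
  cc <- mr_weighted_median(inst, n_boot = 200, seed = 78)
  expect_false(identical(a$se, cc$se))
  m1 <- mr_mode(inst, n_boot = 100, seed = 77)
  m2 <- mr_mode(inst, n_boot = 100, seed = 77)
  expect_identical(m1$se, m2$se)
})

test_that("the suite assembles a results table with shared diagnostics", {
  ss <- gen_two_sample_summary(sim_config(n_snps = 30,
                                          true_causal_effect = 0.1,
                                          seed = 21))
  tab <- run_mr_suite(ss$exposure, ss$outcome, n_boot = 50, seed = 21)
  expect_setequal(tab$method, c("ivw", "egger_intercept", "egger_slope",
                                "weighted_median", "simple_mode",
                                "weighted_mode"))
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))
  expect_equal(length(unique(tab$mean_f)), 1L)
  inst <- attr(tab, "instruments")
  expect_true(all(inst$beta_exp > 0))

  # binary exposure + binary outcome: slope rows are ORs per doubling of odds
  tab2 <- run_mr_suite(ss$exposure, ss$outcome, binary_exposure = TRUE,
                       binary_outcome = TRUE, n_boot = 0, seed = 21)
  raw <- tab[tab$method == "ivw", "beta"]
  expect_equal(tab2[tab2$method == "ivw", "beta"], exp(0.693 * raw),
               tolerance = 1e-12)
  # the Egger intercept is exponentiated but never doubling-rescaled
  expect_equal(tab2[tab2$method == "egger_intercept", "beta"],
               exp(tab[tab$method == "egger_intercept", "beta"]),
               tolerance = 1e-12)
})
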