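# Phenotype derivation, per-SNP association, variant filtering.

test_that("derived phenotypes follow the coding rules", {
  ph <- data.frame(number_of_children = c(0, 2, 1, 0),
                   n_sexual_partners = c(3, 50, 1, 7))
  d <- derive_phenotypes(ph)
  expect_equal(d$childless, c(1, 0, 0, 1))

  # partners 1..100: only the value above the empirical 99th percentile is
  # censored to missing
  ph2 <- data.frame(number_of_children = rep(1, 100),
                    n_sexual_partners = 1:100)
  d2 <- derive_phenotypes(ph2)
  expect_true(is.na(d2$n_sexual_partners[100]))
  expect_equal(sum(is.na(d2$n_sexual_partners)), 1L)
  # the top-partners indicator uses (and reports) the post-censoring 90th
  # percentile cut
  cuts <- attr(d2, "partner_cuts")
  expect_false(is.null(cuts))
  expect_equal(unname(d2$top_partners),
               as.integer(d2$n_sexual_partners >= cuts["top_cut"]))

  expect_warning(
    derive_phenotypes(data.frame(number_of_children = 1:3,
                                 n_sexual_partners = NA_real_)),
    "top_partners")
  expect_error(
    derive_phenotypes(data.frame(number_of_children = 1,
                                 n_sexual_partners = -2)),
    "non-negative")
})

test_that("single-SNP linear association reduces to the OLS slope", {
  co <- gen_cohort(sim_config(n_individuals = 400, n_snps = 4, seed = 6,
                              dosage_missing_rate = 0))
  assoc <- run_association(co, "number_of_children", character(), "linear")
  for (j in 1:4) {
    d <- co$dosages[, j]
    y <- co$phenotypes$number_of_children
    fit <- ols_oracle(cbind(1, d), y)
    expect_equal(assoc$beta[j], fit$coef[2], tolerance = 1e-10)
    expect_equal(assoc$se[j], unname(fit$se[2]), tolerance = 1e-10)
    expect_equal(assoc$eaf[j], mean(d) / 2, tolerance = 1e-12)
  }
})

test_that("a covariate orthogonal to dosage and phenotype leaves beta unchanged", {
  set.seed(14)
  n <- 200
  d <- rbinom(n, 2, 0.3)
  y <- 0.2 * d + rnorm(n)
  # orthogonalize a random vector against the span of (1, d, y)
  z <- rnorm(n)
  z <- residuals(lm(z ~ d + y))
  co <- make_tiny_cohort(
    matrix(d, ncol = 1, dimnames = list(NULL, "rs1")),
    counted = "A", other = "G", risk = "A",
    phenotypes = data.frame(iid = as.character(1:n),
                            number_of_children = y, ortho = z))
  a0 <- run_association(co, "number_of_children", character(), "linear")
  a1 <- run_association(co, "number_of_children", "ortho", "linear")
  expect_equal(a1$beta, a0$beta, tolerance = 1e-8)
})

test_that("association recovers a known per-allele effect and is calibrated at the null", {
  set.seed(50)
  n <- 2000; m <- 60
  maf <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(maf, each = n)), nrow = n,
              dimnames = list(NULL, paste0("rs", 1:m)))
  y <- drop(d %*% rep(0.1, m)) + rnorm(n, 0, 2)
  co <- make_tiny_cohort(d, counted = rep("A", m), other = rep("G", m),
                         risk = rep("A", m),
                         phenotypes = data.frame(iid = as.character(1:n),
                                                 number_of_children = y))
  assoc <- run_association(co, "number_of_children", character(), "linear")
  mc_se <- sd(assoc$beta) / sqrt(m)
  expect_lt(abs(mean(assoc$beta) - 0.1), 3 * mc_se)

  # permuting the phenotype against genotype gives nominal type-I error
  co$phenotypes$number_of_children <- sample(y)
  null_assoc <- run_association(co, "number_of_children", character(),
                                "linear")
  frac <- mean(null_assoc$pval < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m) + 1e-9)
})

test_that("logistic association returns log odds ratios", {
  set.seed(77)
  n <- 3000
  d <- rbinom(n, 2, 0.4)
  eta <- -1 + 0.5 * d
  y <- rbinom(n, 1, plogis(eta))
  co <- make_tiny_cohort(
    matrix(d, ncol = 1, dimnames = list(NULL, "rs1")),
    counted = "A", other = "G", risk = "A",
    phenotypes = data.frame(iid = as.character(1:n),
                            number_of_children = rep(0:2, length.out = n),
                            status = y))
  a <- run_association(co, "status", character(), "logistic")
  ref <- glm(y ~ d, family = binomial())
  expect_equal(a$beta, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(a$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-6)
  expect_error(run_association(co, "number_of_children", character(),
                               "logistic"),
               "binary")
})

test_that("a zero-variance SNP yields a missing record and a warning", {
  d <- matrix(c(1, 1, 1, 1, 0, 1, 2, 1), ncol = 2,
              dimnames = list(NULL, c("rs1", "rs2")))
  co <- make_tiny_cohort(d, counted = c("A", "C"), other = c("G", "T"),
                         risk = c("A", "C"),
                         phenotypes = data.frame(iid = as.character(1:4),
                                                 number_of_children = c(1, 2, 0, 3)))
  expect_warning(a <- run_association(co, "number_of_children", character(),
                                      "linear"),
                 "no estimate")
  expect_true(is.na(a$beta[1]))
  expect_false(is.na(a$beta[2]))
})

test_that("variant filters apply the flat and graded MAF/info rules", {
  mk <- function(eaf, info) data.frame(
    snp = sprintf("s%02d", seq_along(eaf)), effect_allele = "A",
    other_allele = "G", eaf = eaf, beta = 0.1, se = 0.01, pval = 0.5,
    n = 1000, info = info, stringsAsFactors = FALSE)

  # flat: MAF > 0.01 AND info > 0.8
  x <- mk(c(0.005, 0.02, 0.995, 0.3), c(0.95, 0.95, 0.95, 0.7))
  kept <- filter_variants(x, "flat")
  expect_equal(kept$snp, "s02")

  # graded bands
  g <- mk(c(0.02, 0.02, 0.05, 0.05, 0.007, 0.003, 0.0005),
          c(0.65, 0.55, 0.35, 0.25, 0.85, 0.95, 0.99))
  kept_g <- filter_variants(g, "graded")
  expect_setequal(kept_g$snp, c("s01", "s03", "s05", "s06"))

  # missing info is dropped conservatively, and counted
  y <- mk(c(0.3, 0.3), c(NA, 0.9))
  kept_y <- filter_variants(y, "flat")
  expect_equal(kept_y$snp, "s02")
  expect_equal(unname(attr(kept_y, "filter_log")["dropped_missing_info"]), 1)

  # idempotence
  twice <- filter_variants(filter_variants(g, "graded"), "graded")
  expect_equal(twice$snp, kept_g$snp)
})
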