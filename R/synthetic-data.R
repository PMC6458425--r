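# Synthetic-data generators.
#
# These emulate the two kinds of input the MR pipeline consumes: GWAS summary
# statistics for a two-sample design, and an individual-level cohort
# (genotype dosages + reproductive phenotypes + covariates) for the
# score-based sensitivity analyses.  The causal architecture is known, so
# every downstream stage can be tested against ground truth.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic-data generators.
#' Defaults describe the study conditions the package is calibrated to:
#' a post-reproductive population cohort (children 1.8 +/- 1.2, lifetime
#' sexual partners 5.8 +/- 8.6, age at first birth 25.4 +/- 4.5 in parous
#' females), instruments jointly explaining 3.4% of liability variance, and
#' exposure/outcome GWAS sample sizes of roughly 145k and 336k.
#'
#' @param n_individuals cohort size (>= 2).
#' @param n_snps number of instrument SNPs (>= 1).
#' @param maf_range interval in (0, 0.5] for per-SNP minor allele frequency.
#' @param true_causal_effect causal effect of the (standardized genetic)
#'   liability on each outcome, in outcome units per SD of liability.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects)
#'   or `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of the per-SNP direct
#'   (horizontal-pleiotropy) effect on the outcome, for invalid instruments.
#' @param invalid_fraction proportion of instruments given a direct effect.
#' @param exposure_h2 proportion of liability variance the instruments
#'   jointly explain.
#' @param nonlinearity shape of the liability-to-fitness map: `"linear"`,
#'   `"quadratic"`, or `"cliff_edge"`.
#' @param quadratic_coef coefficient on squared standardized genetic
#'   liability under `nonlinearity = "quadratic"` (negative = intermediate
#'   optimum).
#' @param cliff_threshold_quantile liability quantile above which the cliff
#'   penalty applies.
#' @param cliff_penalty outcome-unit shift applied beyond the cliff
#'   (negative = fitness cost).
#' @param n_exposure_sample,n_outcome_sample GWAS sample sizes of the two
#'   (independent) summary-statistic samples.
#' @param palindromic_rate proportion of SNPs given palindromic (A/T or G/C)
#'   allele pairs, to exercise harmonization policy.
#' @param allele_swap_fraction proportion of outcome records emitted with
#'   swapped effect/other alleles (and sign-flipped effect), to exercise
#'   harmonization.
#' @param dosage_missing_rate proportion of dosage entries set missing.
#' @param case_prevalence liability-threshold prevalence for the disorder
#'   case flag (the cohort analyses can be repeated excluding cases).
#' @param seed master seed; all stages derive substreams from it via
#'   [substream_seed()].
#' @return an object of class `"sim_config"` (a validated list).
#' @seealso [gen_cohort()], [gen_two_sample_summary()]
#' @export
sim_config <- function(n_individuals = 20000L,
                       n_snps = 100L,
                       maf_range = c(0.05, 0.5),
                       true_causal_effect = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       invalid_fraction = 0,
                       exposure_h2 = 0.034,
                       nonlinearity = c("linear", "quadratic", "cliff_edge"),
                       quadratic_coef = -0.05,
                       cliff_threshold_quantile = 0.9,
                       cliff_penalty = -1,
                       n_exposure_sample = 144780L,
                       n_outcome_sample = 335758L,
                       palindromic_rate = 0.1,
                       allele_swap_fraction = 0.3,
                       dosage_missing_rate = 0.02,
                       case_prevalence = 0.004,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  nonlinearity <- match.arg(nonlinearity)
  if (!is.numeric(n_individuals) || n_individuals < 2)
    stop("invalid config: n_individuals must be >= 2")
  if (!is.numeric(n_snps) || n_snps < 1)
    stop("invalid config: n_snps must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("invalid config: maf_range must lie within (0, 0.5]")
  props <- c(invalid_fraction = invalid_fraction, exposure_h2 = exposure_h2,
             palindromic_rate = palindromic_rate,
             allele_swap_fraction = allele_swap_fraction,
             dosage_missing_rate = dosage_missing_rate,
             case_prevalence = case_prevalence)
  bad <- props < 0 | props > 1
  if (any(bad))
    stop("invalid config: ", paste(names(props)[bad], collapse = ", "),
         " must lie in [0,1]")
  if (cliff_threshold_quantile <= 0 || cliff_threshold_quantile >= 1)
    stop("invalid config: cliff_threshold_quantile must lie in (0,1)")
  if (pleiotropy_sd < 0) stop("invalid config: pleiotropy_sd must be >= 0")
  if (dosage_missing_rate >= 1)
    stop("invalid config: dosage_missing_rate must be < 1")
  if (n_exposure_sample < 2 || n_outcome_sample < 2)
    stop("invalid config: GWAS sample sizes must be >= 2")
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    true_causal_effect = true_causal_effect,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, invalid_fraction = invalid_fraction,
    exposure_h2 = exposure_h2, nonlinearity = nonlinearity,
    quadratic_coef = quadratic_coef,
    cliff_threshold_quantile = cliff_threshold_quantile,
    cliff_penalty = cliff_penalty,
    n_exposure_sample = as.integer(n_exposure_sample),
    n_outcome_sample = as.integer(n_outcome_sample),
    palindromic_rate = palindromic_rate,
    allele_swap_fraction = allele_swap_fraction,
    dosage_missing_rate = dosage_missing_rate,
    case_prevalence = case_prevalence, seed = as.integer(seed)),
    class = "sim_config")
}

# shared genetic architecture: MAF, allele labels, per-SNP liability weights.
# Drawn from the "architecture" substream so cohort and summary generators
# built from the same config describe the same instruments.
draw_architecture <- function(config) {
  seed_stage(config$seed, "architecture")
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  palindromic <- stats::runif(m) < config$palindromic_rate
  effect_allele <- sample(BASES, m, replace = TRUE)
  other_allele <- character(m)
  other_allele[palindromic] <- COMPLEMENT[effect_allele[palindromic]]
  for (j in which(!palindromic)) {
    choices <- setdiff(BASES, c(effect_allele[j], COMPLEMENT[effect_allele[j]]))
    other_allele[j] <- sample(choices, 1L)
  }
  v <- 2 * maf * (1 - maf)
  # instrument-grade effects: magnitudes bounded away from zero (published
  # instrument tables contain only genome-wide-significant SNPs) and
  # inversely related to allele-frequency variance, as selection induces;
  # then scaled so the instruments jointly explain exposure_h2 of a
  # unit-variance liability
  w <- (1 + abs(stats::rnorm(m))) * sample(c(-1, 1), m, replace = TRUE) /
    sqrt(v)
  w <- w * sqrt(config$exposure_h2 / sum(w^2 * v))
  invalid <- rep(FALSE, m)
  n_invalid <- round(config$invalid_fraction * m)
  if (n_invalid > 0) invalid[sample.int(m, n_invalid)] <- TRUE
  list(snp = sprintf("rs%06d", seq_len(m)), maf = maf,
       effect_allele = effect_allele, other_allele = other_allele,
       palindromic = palindromic, weight = w, var_snp = v, invalid = invalid)
}

# fitness map applied to the standardized total liability
liability_map <- function(liab, config) {
  base <- config$true_causal_effect * liab
  switch(config$nonlinearity,
    linear = base,
    quadratic = base + config$quadratic_coef * liab^2,
    cliff_edge = base + config$cliff_penalty *
      (liab > stats::qnorm(config$cliff_threshold_quantile)))
}

#' Generate an individual-level cohort with known liability architecture
#'
#' Draws per-SNP dosages under Hardy-Weinberg equilibrium, builds a weighted
#' genetic liability score standardized to unit variance, and generates
#' reproductive phenotypes (number of children, lifetime sexual partners,
#' age at first birth) from the configured liability-to-fitness map plus
#' covariate effects and Gaussian noise, rounded to non-negative counts where
#' applicable.  Age at first birth is generated only for parous females.
#'
#' Total liability is the standardized genetic score (explaining
#' `exposure_h2` of its variance) plus environmental noise; the fitness map
#' (linear, quadratic or cliff-edge) and the disorder threshold at
#' `config$case_prevalence` both act on total liability, the genetic score
#' being only the analysis-side proxy for it.  The returned phenotype table
#' carries `truth_genetic_score` and `truth_liability` columns so tests can
#' condition on ground truth.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `"cohort_table"`: a list with elements
#'   `dosages` (individuals x SNPs matrix, values 0-2 with `NA` holes),
#'   `snp_info` (per-SNP counted/other/risk alleles and MAF), and
#'   `phenotypes` (one row per individual: `iid`, `sex` (female = 0,
#'   male = 1), `age`, `pc1`..`pc10`, `number_of_children`,
#'   `age_at_first_birth`, `n_sexual_partners`, `case_flag`,
#'   `truth_genetic_score`).
#' @examples
#' cohort <- gen_cohort(sim_config(n_individuals = 500, n_snps = 20))
#' str(cohort$phenotypes)
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  arch <- draw_architecture(config)

  seed_stage(config$seed, "cohort_genotypes")
  dos <- matrix(stats::rbinom(n * m, 2L, rep(arch$maf, each = n)), nrow = n,
                dimnames = list(NULL, arch$snp))
  g <- as.vector(sweep(dos, 2L, 2 * arch$maf) %*% arch$weight)
  g <- g / sqrt(sum(arch$weight^2 * arch$var_snp))  # standardized genetic score

  seed_stage(config$seed, "cohort_phenotypes")
  sex <- stats::rbinom(n, 1L, 0.5)            # female = 0, male = 1
  age <- round(stats::runif(n, 40, 70))
  pcs <- matrix(stats::rnorm(n * 10L), nrow = n,
                dimnames = list(NULL, paste0("pc", 1:10)))
  # total liability: genetic score plus environmental noise, unit variance;
  # the fitness map and the disorder threshold both act on it, the genetic
  # score being the analysis-side proxy
  h2 <- config$exposure_h2
  liability <- sqrt(h2) * g + sqrt(1 - h2) * stats::rnorm(n)
  f <- liability_map(liability, config)
  children <- pmax(0, round(1.8 + f + 0.01 * (age - 55) + 0.02 * pcs[, 1] +
                              stats::rnorm(n, 0, 1.2)))
  partners <- pmax(0, round(5.8 + f + 1.5 * sex - 0.05 * (age - 55) +
                              stats::rnorm(n, 0, 8.6)))
  afb <- round(25.4 + f + stats::rnorm(n, 0, 4.5))
  afb[sex == 1L | children == 0] <- NA_real_  # measured in parous females only
  afb <- pmax(afb, 14, na.rm = FALSE)
  case_flag <- as.integer(liability > stats::qnorm(1 - config$case_prevalence))

  seed_stage(config$seed, "cohort_missingness")
  partners[stats::runif(n) < 0.02] <- NA_real_
  if (config$dosage_missing_rate > 0) {
    holes <- stats::runif(n * m) < config$dosage_missing_rate
    dos[matrix(holes, nrow = n)] <- NA_integer_
  }

  snp_info <- data.frame(
    snp = arch$snp,
    counted_allele = arch$effect_allele,  # allele counted by the dosage
    other_allele = arch$other_allele,
    maf = arch$maf,
    risk_allele = ifelse(arch$weight >= 0, arch$effect_allele,
                         arch$other_allele),
    truth_weight = arch$weight,
    stringsAsFactors = FALSE)

  phenotypes <- data.frame(
    iid = sprintf("id%06d", seq_len(n)), sex = sex, age = age, pcs,
    number_of_children = as.numeric(children),
    age_at_first_birth = as.numeric(afb),
    n_sexual_partners = as.numeric(partners),
    case_flag = case_flag, truth_genetic_score = g,
    truth_liability = liability,
    stringsAsFactors = FALSE)

  structure(list(dosages = dos, snp_info = snp_info, phenotypes = phenotypes,
                 config = config),
            class = "cohort_table")
}

#' Generate two-sample GWAS summary statistics with known causal effect
#'
#' Per-SNP exposure effects come from the shared genetic architecture with
#' standard errors `1/sqrt(2 maf (1-maf) n_exposure_sample)`; the outcome
#' effect for SNP j is `true_causal_effect * beta_exp_j + alpha_j + noise`,
#' where `alpha_j` is zero for valid instruments and drawn per
#' `pleiotropy_mode` for the `invalid_fraction` of invalid ones.  The
#' exposure and outcome samples use disjoint noise substreams (two-sample
#' design, no shared individuals).  A fraction `allele_swap_fraction` of
#' outcome records is emitted with swapped effect/other alleles, sign-flipped
#' effect and complemented frequency, to exercise harmonization.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `exposure` and `outcome`, each a summary-
#'   statistics data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `info`, plus a
#'   `truth` data.frame (per-SNP true effects, pleiotropy, validity).
#' @examples
#' ss <- gen_two_sample_summary(sim_config(n_snps = 50,
#'                                         true_causal_effect = 0.1))
#' head(ss$exposure)
#' @export
gen_two_sample_summary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  arch <- draw_architecture(config)
  m <- config$n_snps
  # emit records oriented to the exposure-increasing (risk) allele, as
  # published instrument tables are
  risk_flip <- arch$weight < 0
  beta_exp_true <- abs(arch$weight)
  eff_allele <- ifelse(risk_flip, arch$other_allele, arch$effect_allele)
  oth_allele <- ifelse(risk_flip, arch$effect_allele, arch$other_allele)
  freq <- ifelse(risk_flip, 1 - arch$maf, arch$maf)

  seed_stage(config$seed, "exposure_sample")
  se_exp <- 1 / sqrt(arch$var_snp * config$n_exposure_sample)
  beta_exp <- beta_exp_true + stats::rnorm(m, 0, se_exp)
  info_exp <- round(stats::runif(m, 0.85, 1), 3)

  seed_stage(config$seed, "outcome_sample")
  alpha <- numeric(m)
  if (config$pleiotropy_mode != "none" && any(arch$invalid)) {
    mu <- if (config$pleiotropy_mode == "directional") config$pleiotropy_mean else 0
    alpha[arch$invalid] <- stats::rnorm(sum(arch$invalid), mu,
                                        config$pleiotropy_sd)
  }
  beta_out_true <- config$true_causal_effect * beta_exp_true + alpha
  se_out <- 1 / sqrt(arch$var_snp * config$n_outcome_sample)
  beta_out <- beta_out_true + stats::rnorm(m, 0, se_out)
  eaf_out <- pmin(pmax(freq + stats::rnorm(m, 0, 0.005), 0.001), 0.999)
  info_out <- round(stats::runif(m, 0.85, 1), 3)
  swapped <- stats::runif(m) < config$allele_swap_fraction

  exposure <- data.frame(
    snp = arch$snp, effect_allele = eff_allele,
    other_allele = oth_allele, eaf = freq,
    beta = beta_exp, se = se_exp,
    pval = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    n = config$n_exposure_sample, info = info_exp,
    stringsAsFactors = FALSE)

  outcome <- data.frame(
    snp = arch$snp,
    effect_allele = ifelse(swapped, oth_allele, eff_allele),
    other_allele = ifelse(swapped, eff_allele, oth_allele),
    eaf = ifelse(swapped, 1 - eaf_out, eaf_out),
    beta = ifelse(swapped, -beta_out, beta_out), se = se_out,
    pval = 2 * stats::pnorm(-abs(beta_out / se_out)),
    n = config$n_outcome_sample, info = info_out,
    stringsAsFactors = FALSE)

  truth <- data.frame(snp = arch$snp, beta_exp_true = beta_exp_true,
                      beta_out_true = beta_out_true, alpha = alpha,
                      invalid = arch$invalid, swapped = swapped,
                      stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Generate a synthetic LD-score panel for two traits
#'
#' Per-SNP LD scores are drawn from a right-skewed positive distribution
#' (1 + gamma).  Z-score pairs follow the bivariate model
#' `E[z1^2] = 1 + N1 h2_1 l_j / M`,
#' `E[z1 z2] = overlap + sqrt(N1 N2) rg sqrt(h2_1 h2_2) l_j / M`.
#'
#' @param M number of SNPs.
#' @param h2_1,h2_2 SNP-heritabilities of the two traits, in `[0, 1]`.
#' @param rg genetic correlation, in `[-1, 1]`.
#' @param N1,N2 GWAS sample sizes.
#' @param seed integer seed.
#' @param overlap constant added to the cross-trait expectation
#'   (sample-overlap confounding; default 0).
#' @return a data.frame of class `"ldsc_panel"` with columns `snp`, `l2`,
#'   `z1`, `z2`, `n1`, `n2`; attribute `M` is the SNP count.
#' @examples
#' panel <- gen_ldsc_panel(M = 1000, h2_1 = 0.4, h2_2 = 0.3, rg = 0.5,
#'                         N1 = 50000, N2 = 50000, seed = 1)
#' @export
gen_ldsc_panel <- function(M, h2_1, h2_2, rg, N1, N2, seed, overlap = 0) {
  if (abs(rg) > 1) stop("generation error: |rg| must be <= 1 (got ", rg, ")")
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1)
    stop("generation error: heritabilities must lie in [0,1] (got h2_1 = ",
         h2_1, ", h2_2 = ", h2_2, ")")
  N1 <- as.numeric(N1); N2 <- as.numeric(N2)
  seed_stage(seed, "ldsc_panel")
  l2 <- 1 + stats::rgamma(M, shape = 2, rate = 2 / 60)
  s11 <- 1 + N1 * h2_1 * l2 / M
  s22 <- 1 + N2 * h2_2 * l2 / M
  s12 <- overlap + sqrt(N1 * N2) * rg * sqrt(h2_1 * h2_2) * l2 / M
  resid22 <- s22 - s12^2 / s11
  if (any(resid22 < -1e-12))
    stop("generation error: per-SNP covariance not positive semi-definite ",
         "(h2_1 = ", h2_1, ", h2_2 = ", h2_2, ", rg = ", rg,
         ", overlap = ", overlap, ")")
  resid22 <- pmax(resid22, 0)
  e1 <- stats::rnorm(M)
  e2 <- stats::rnorm(M)
  z1 <- sqrt(s11) * e1
  z2 <- (s12 / sqrt(s11)) * e1 + sqrt(resid22) * e2
  panel <- data.frame(snp = sprintf("rs%07d", seq_len(M)), l2 = l2,
                      z1 = z1, z2 = z2, n1 = N1, n2 = N2,
                      stringsAsFactors = FALSE)
  attr(panel, "M") <- as.integer(M)
  class(panel) <- c("ldsc_panel", "data.frame")
  panel
}
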