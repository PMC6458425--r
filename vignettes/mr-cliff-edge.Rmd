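---
title: "Methods: two-sample MR for liability and fitness, with cliff-edge sensitivity analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for liability and fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliffmr)
```

## The scientific question

Heritable psychiatric disorders that reduce the fertility of those diagnosed
pose an evolutionary puzzle: why does common risk variation persist?  One
candidate answer is *cliff-edge fitness*: reproductive success rises (or at
least does not fall) with genetic liability among unaffected carriers, and
only collapses beyond a liability threshold near diagnosis, so the
advantage below the cliff offsets the cost beyond it.  cliffmr implements
the two complementary ways this is probed with modern genetic data:

1. **Two-sample Mendelian randomization (MR).**  SNPs robustly associated
   with liability serve as instrumental variables.  Because alleles are
   assigned at conception, per-allele contrasts in a fitness outcome
   estimate the causal effect of liability free of most confounding and of
   reverse causation, using only summary statistics from two non-overlapping
   GWAS samples.
2. **Individual-level score analyses.**  An unweighted risk-allele count
   per person supports quantile fitness curves, quadratic regressions, and
   regressions that repeatedly discard the top tail of the score — the
   machinery that would reveal a decline confined to high liability, which
   a linear MR estimate would average away.

A simplified LD score regression supplies genome-wide genetic correlations
as the observational complement.

## The MR estimator suite

Each harmonized instrument $j$ contributes exposure and outcome effects
$(\hat\beta_{Xj}, \hat\beta_{Yj})$ with standard errors
$(\sigma_{Xj}, \sigma_{Yj})$, oriented so $\hat\beta_{Xj} > 0$
(the liability-increasing allele convention).  With weights
$w_j = 1/\sigma_{Yj}^2$:

* **IVW** solves the zero-intercept weighted regression of outcome on
  exposure effects:
  $\hat\theta = \sum w_j \hat\beta_{Yj}\hat\beta_{Xj} \big/ \sum w_j \hat\beta_{Xj}^2$,
  fixed-effect SE $1/\sqrt{\sum w_j \hat\beta_{Xj}^2}$.  Cochran's
  $Q = \sum w_j (\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$ measures
  overdispersion, and the multiplicative random-effects SE inflates the
  fixed SE by $\max(1, \sqrt{Q/(k-1)})$.  The same inflation (with
  $k - 2$ degrees of freedom) applies to MR-Egger.  We chose the
  multiplicative random-effects flavour because the cited methodology
  names "the random effect" without a formula, and SE inflation floored at
  one is the convention of the IVW/Egger literature it cites.
* **MR-Egger** frees the intercept; the intercept estimates average
  directional pleiotropy and the slope remains consistent under the InSIDE
  assumption (instrument strength independent of direct effects).
* **Weighted median**: per-SNP ratio estimates
  $\hat\beta_{Yj}/\hat\beta_{Xj}$ are sorted; with ratio weights
  $\hat\beta_{Xj}^2/\sigma_{Yj}^2$ the estimate is the value at which the
  normalized cumulative weight crosses $1/2$, linearly interpolated between
  bracketing ratios at their cumulative-weight midpoints.  Consistent when
  at least half the weight comes from valid instruments.  Its SE comes from
  a seeded parametric bootstrap (default 1000 draws): effects are redrawn
  from $N(\hat\beta, \sigma)$ per SNP and the estimator recomputed — the
  cited methodology reports no analytic SE for this estimator.
* **Mode-based estimators** (simple and weighted): the argmax of a
  normal-kernel density over the ratio estimates, bandwidth
  $\varphi \times 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,k^{-1/5}$ with the
  tuning parameter $\varphi = 0.5$ by default.  The argmax is located on a
  10,000-point grid spanning the ratio range padded by three bandwidths;
  ties break to the smallest grid value; identical ratios short-circuit to
  that ratio with zero SE, flagged degenerate.  SEs are bootstrap, as
  above.

Diagnostics: the mean F statistic
$\frac{1}{k}\sum \hat\beta_{Xj}^2/\sigma_{Xj}^2$ (above 10 is the
conventional adequacy bar) and $I^2_{GX}$, which quantifies the regression
dilution of the MR-Egger slope from measurement error in the exposure
effects (above 0.9 desired; the unweighted variant scales unit weights by
the mean squared exposure SE).  One printed description of the F statistic
in the methodological literature places the *outcome* SE in the denominator; the
standard instrument-strength F uses the exposure SE, and that is what is
implemented — the discrepancy is deliberate and documented rather than
silently followed.

**Scale conventions.**  A binary-liability exposure expressed in log odds
yields estimates per unit log odds; multiplying by 0.693 (ln 2 at the
conventional three decimals) re-expresses them per *doubling* of the odds
of the exposure.  For binary outcomes the (rescaled) log odds ratio is
exponentiated.  Both transitions are guarded by a scale field so they
cannot be applied twice.  The MR-Egger intercept measures pleiotropy per
SNP, not per unit exposure, so it is exponentiated for binary outcomes but
never multiplied by 0.693.  Confidence intervals use the normal 1.96
multiplier on the estimation scale throughout, before any exponentiation.

## Harmonization

Exposure and outcome records are matched by SNP id and aligned to a shared
effect allele: a swapped label pair flips the outcome effect sign and
complements its frequency; strand-complement labels are complemented first;
incompatible pairs and SNPs present in only one study are excluded with
recorded reasons.  Palindromic variants (A/T, G/C) cannot be aligned from
labels alone.  The default policy (`infer_by_eaf`) aligns them by
minor-allele matching when both frequencies fall outside an ambiguity
window of [0.42, 0.58], and excludes them inside it; `drop_ambiguous`
behaves identically (the window is where the two policies coincide) and
`keep` trusts the labels.  The window and policy are configurable because
the original analysis is silent on palindromes; [0.42, 0.58] is common
two-sample MR practice.  Finally both studies are re-oriented to the
exposure-increasing allele.  Harmonization is idempotent, and every MR
estimate downstream is invariant to relabelling outcome alleles (with the
corresponding sign flips), which the test suite checks property-style.

## GWAS engine and filters

Outcome phenotypes follow the original cohort's derivations: childlessness is
`number_of_children == 0`; lifetime sexual-partner counts strictly above
their empirical 99th percentile are censored to missing; a top-partners
indicator marks the (post-censoring) top decile, with the cut actually used
reported alongside.  Associations are per-SNP least squares (or logistic
regression for the binary outcomes, so that exponentiated effects are
genuine odds ratios — the original study reports ORs without naming the binary
model family) with complete-case handling per analysis, dosage coefficient
SEs from the QR fit, and two-sided Wald p-values.  Variant filters come in
the two forms the original study uses: a flat rule (MAF > 0.01 and imputation info
> 0.8) and a graded rule demanding better imputation for rarer variants
(info > 0.3 above 3% MAF, > 0.6 for 1–3%, > 0.8 for 0.5–1%, > 0.9 for
0.1–0.5%, nothing below 0.1%).  Records lacking info are dropped and
counted — the conservative reading.

## Score sensitivity analyses

The genetic score is the plain sum of risk-allele dosages (no effect-size
weights, which keeps sex-stratified reruns unbiased when instrument effects
come from a mixed-sex GWAS), with missing dosages mean-imputed per SNP.
Quantile summaries use stable-rank ties and equal bin counts (±1), with the
transposed outcome-binned view also emitted.  The tail-removal scan drops
individuals above the $1 - f$ score quantile for each removal fraction
$f$ and refits `outcome ~ score + covariates`; a coefficient that rises as
the tail is removed is the cliff signature.  Quadratic fits center the
score before squaring for conditioning and report coefficients on the
raw-score scale via the polynomial identity, plus the stationary point
$-b/(2a)$; per-sex fits drop the sex covariate within strata.  Covariate
sets mirror the original study's tables: the scan adjusts for 10 principal
components only; quadratic fits add age and sex where the outcome warrants
it.

## The synthetic-data generators

Because the real cohort and consortium statistics cannot be redistributed,
every analysis is exercised on generated data with known architecture.
Key choices, fixed as study conditions:

* **Cohort moments** mirror the original study's descriptives: children 1.8 ± 1.2,
  partners 5.8 ± 8.6 (both rounded, floored at zero — the original study analyses
  them with linear regression, so Gaussian machinery suffices), age at
  first birth 25.4 ± 4.5 generated only for parous females, age ~
  U(40, 70), ten standard-normal PCs (pc1 given a small real effect on
  fertility so adjustment matters), sex balanced with female = 0.
* **Liability model**: dosages are binomial(2, MAF) with MAF ~ U(0.05,
  0.5); the genetic score explains `exposure_h2` (default 0.034, the share
  the original instruments explain) of a unit-variance *total* liability;
  the fitness map — linear, quadratic, or cliff-edge — and the disorder
  threshold (prevalence 0.004, giving the handful of cases the
  case-exclusion rerun needs) act on total liability, of which the genetic
  score is the observable proxy.  Truth columns
  (`truth_genetic_score`, `truth_liability`) are emitted for testing.
* **Instrument-grade effects**: per-SNP effect magnitudes are drawn
  bounded away from zero ($1 + |N(0,1)|$) and inversely proportional to
  $\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}$, then rescaled to
  `exposure_h2`.  Published instrument tables contain only
  genome-wide-significant SNPs, and allowing near-zero effects would let
  the orientation step flip instruments on noise — which spuriously
  converts directional pleiotropy into balanced.  Summary records are
  emitted oriented to the risk allele, as real tables are.
* **Two-sample design**: exposure and outcome effect noise use disjoint
  seed substreams (every stage's seed is a stable hash of the master seed
  and the stage name), with SEs $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})N}$
  at the study-matched sample sizes (144,780 exposure; 335,758 outcome).
  Pleiotropy adds per-SNP direct effects to an `invalid_fraction` of
  instruments — mean-zero (balanced) or mean `pleiotropy_mean`
  (directional, independent of instrument strength, so InSIDE holds).
  A configurable fraction of outcome records (default 0.3) is emitted with
  swapped allele labels, and about 10% of SNPs are palindromic, so
  harmonization is always exercised.
* **LD-score panels** draw positive right-skewed LD scores and z-score
  pairs from the standard bivariate moment model
  $E[z_1^2] = 1 + N_1 h_1^2 \ell_j / M$,
  $E[z_1 z_2] = \sqrt{N_1 N_2}\, r_g \sqrt{h_1^2 h_2^2}\, \ell_j / M$
  (plus an optional constant for sample overlap), rejecting parameter
  combinations whose per-SNP covariance is not positive semi-definite.

What the generators do **not** emulate: linkage disequilibrium between
instruments (the original study uses independent SNPs), genotyping batch effects,
imputation error beyond an info column, ascertainment/participation bias,
and count-specific error distributions.  Passing tests therefore certify
the estimators and machinery, not robustness to those real-data features.

## Simplified LD score regression

Squared (and cross-) z-scores are regressed on LD scores by ordinary least
squares; heritability is slope × M/N, genetic covariance is
slope × M/√(N₁N₂), and $r_g$ their ratio against the univariate
heritabilities.  Standard errors are delete-one block jackknives over 200
contiguous blocks, with the $r_g$ jackknife recomputing all three
regressions per deletion.  The reference implementations add iterative
heteroskedasticity weighting and read genome-wide reference LD files; at
synthetic scale OLS with jackknife SEs recovers the generating parameters
well within its own error, so the extra machinery is out of scope here.
Negative fitted heritabilities and $|r_g| > 1$ are flagged, never
truncated, to keep the estimator's unbiasedness testable.  Real
genome-wide genetic correlations for the original traits are not
reproducible without external reference data; the pipeline reproduces the
table's *shape* on synthetic panels.

## Numerical choices and problem sizes

Tests and the acceptance script size their simulations to run on a laptop
core in a couple of minutes each: estimator consistency uses 50
instruments × 100–200 replicates; the estimator-consistency check uses an
exposure GWAS of $10^6$ so weak-instrument attenuation — a genuine
finite-sample property of IVW of order $M/(N h^2)$, about 1% at the
source-matched sample size — is negligible relative to Monte-Carlo error;
the pleiotropy-recovery check stays at the study-matched size, where the
Egger intercept is already unbiased.  The nonlinearity power checks run at
n = 20,000 individuals × 100 SNPs in a deliberately favourable regime:
`exposure_h2 = 0.5`, a cliff beginning at the top liability *quintile*
(family-study arguments place fitness decline at sub-diagnostic
liability), and a penalty of −1.8 children — complete loss of expected
fitness beyond the cliff.  These were fixed by an a-priori power analysis
of the expected scan curve under the bivariate-normal liability model; at
the realistic `exposure_h2 = 0.034` the scan and quadratic fits are
correctly powerless, which mirrors the original study's own null findings
and is a statement about the data, not the method.  LD score panels use
M = 20,000.

Degenerate inputs are handled explicitly rather than left to fail:
zero-variance dosages yield missing association records with a warning;
identical ratio estimates short-circuit the mode estimator; collinear
Egger designs and empty retained sets raise informative errors; the
random-effects SE never undercuts the fixed-effect SE.

## Known limitations

* No SIMEX correction for MR-Egger dilution, no MR-PRESSO/Steiger
  filtering, no multivariable MR, and no LD-proxy lookup — instruments are
  consumed as a final list.
* The weighted-median and mode SEs are bootstrap-only; coverage of those
  intervals inherits bootstrap error at small k.
* The LDSC module is a teaching-scale estimator: no heteroskedasticity
  weights, no reference panels, no attenuation-ratio diagnostics.
* Count outcomes are modelled as rounded truncated Gaussians, which
  slightly compresses effects near zero children; the analytic oracles in
  the test suite account for this.
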