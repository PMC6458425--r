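Package: cliffmr
Title: Two-Sample Mendelian Randomization with Cliff-Edge Fitness
    Sensitivity Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates causal effects of genetic liability on reproductive
    outcomes from GWAS summary statistics using a suite of two-sample
    Mendelian randomization estimators (inverse-variance weighted, MR-Egger,
    weighted median, and mode-based), with allele harmonization, instrument
    strength diagnostics (mean F, I2GX, Cochran's Q) and per-doubling-of-odds
    rescaling for binary exposures.  Includes individual-level machinery for
    probing nonlinear (cliff-edge) liability-to-fitness relationships via
    unweighted genetic scores, quantile fitness curves, cumulative
    tail-removal regression scans and quadratic fits; a simplified LD score
    regression for genetic correlation; seeded synthetic-data generators for
    cohorts, summary statistics and LD score panels with known ground truth;
    and a configuration-driven pipeline reproducing the full analysis
    surface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
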