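Package: smokemr
Title: Lifetime Smoking Index and Two-Sample Mendelian Randomisation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs a lifetime smoking exposure index that combines
    smoking status, duration, heaviness and time since cessation through an
    exponential half-life decay, and calibrates the half-life constant
    against a binary (or time-to-event) health outcome. Implements
    bi-directional two-sample Mendelian randomisation on GWAS summary
    statistics: instrument selection with distance/LD clumping, allele
    harmonisation with palindromic-variant resolution and proxy
    substitution, and causal-effect estimation by inverse-variance
    weighting, MR-Egger (with SIMEX measurement-error correction), weighted
    median, weighted mode and robust adjusted profile score (RAPS),
    together with Cochran's Q, I2_GX, mean F and Steiger directionality
    diagnostics. Ships seeded synthetic-data generators for smoking
    cohorts and GWAS summary statistics with known ground truth, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
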