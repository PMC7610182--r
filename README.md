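# smokemr

Bi-directional two-sample Mendelian randomisation (MR) for smoking and
health outcomes, built around a **lifetime smoking index** — a continuous
exposure score that combines smoking status, duration, intensity and time
since cessation, so MR can be run on unstratified GWAS samples instead of
having to split smokers from non-smokers.

The package is for epidemiologists and statistical geneticists who work
with GWAS summary statistics. It provides:

* the lifetime smoking index and the calibration of its half-life
  constant against a health outcome;
* summary-statistic ingestion, instrument selection (p < 5×10⁻⁸,
  clumping at r² = 0.001 within 10,000 kb), allele harmonisation with
  palindromic-variant resolution (MAF < 0.3 rule) and proxy substitution
  (r² ≥ 0.8);
* five causal estimators — IVW (main analysis), MR-Egger with SIMEX
  measurement-error correction, weighted median, weighted mode, and
  RAPS — plus Cochran's Q, the Egger intercept, mean F, I²GX and Steiger
  directionality diagnostics;
* seeded synthetic-data generators (GWAS summary statistics with known
  causal effect and configurable pleiotropy; smoking cohorts with a
  linked outcome) so every stage is testable end to end;
* `runPipeline()`, which orchestrates the bi-directional analysis and
  writes result tables, drop logs and a reproducibility manifest.

## The models in brief

**Lifetime smoking index.** For duration `dur` (years), time since
cessation `tsc` (years), intensity `cpd` (cigarettes/day) and half-life
τ:

    S = (1 − 0.5^(dur/τ)) · 0.5^(tsc/τ) · ln(cpd + 1)

Never smokers score 0; the score saturates in duration, decays after
quitting, and is capped by ln(cpd+1). τ is calibrated by scanning a grid
and maximising the log-likelihood of a single-predictor logistic (or Cox)
model of a health outcome on the score; τ = 18 years is the calibrated
default.

**Two-sample MR.** With per-variant SNP-exposure effects γ̂ⱼ (se σ_γⱼ)
and allele-aligned SNP-outcome effects Γ̂ⱼ (se σ_Γⱼ), IVW is the weighted
regression of Γ̂ on γ̂ through the origin with weights 1/σ_Γ²; MR-Egger
adds an intercept (the directional-pleiotropy estimate); the weighted
median/mode act on the Wald ratios Γ̂ⱼ/γ̂ⱼ; RAPS profiles the causal
effect from residuals standardised by √(σ_Γ² + β²σ_γ²). Both regressions
use multiplicative random-effects scaling max(1, √(Q/df)). When I²GX
falls below 0.9, the Egger slope is additionally SIMEX-corrected
(unweighted, quadratic extrapolation to λ = −1).

## Worked example

Score the two reference smoking histories (each designed to equal one
standard deviation of lifetime smoking exposure):

```r
library(smokemr)
lifetimeSmokingIndex(c(15, 13), c(17, 22), c(20, 60), tau = 18)
#> [1] 0.6941431 0.6939450
```

Both histories — 20 a day for 15 years quit 17 years ago, and 60 a day
for 13 years quit 22 years ago — score 0.694, the population SD of the
index.

Run a full MR analysis on a synthetic exposure/outcome GWAS pair with a
known causal odds ratio of 2 (log-OR 0.693):

```r
sim <- simulateSummaryStats(simulationConfig(
  theta = log(2), n_snp = 80, gamma_mean = 0.03, gamma_scale = 0.005,
  seed = 42))
instruments <- selectInstruments(sim$exposure)
h <- harmoniseData(instrumentRecords(instruments), sim$outcome)
h
#> HarmonisedDataset: 77 variants retained, 3 dropped
#>   flipped: 29  palindromic kept: 5  proxied: 0
#>   mean F statistic: 162.3
#>   drop reasons: palindromic_maf (3)

runMR(h, outcome_type = "binary", config = mrConfig(seed = 1))
#> Two-sample MR results (binary outcome, 77 variants)
#>           method n_snp  beta     se ci_low ci_high      pval note   or or_ci_low or_ci_high
#>              IVW    77 0.683 0.0160  0.651   0.715  6.11e-55      1.98      1.92       2.04
#>            Egger    77 0.481 0.0896  0.303   0.660  8.59e-07      1.62      1.36       1.93
#>      Egger-SIMEX    77 0.636 0.1030  0.430   0.841  3.31e-08      1.89      1.54       2.31
#>  Weighted median    77 0.658 0.0238  0.611   0.704 1.20e-168      1.93      1.84       2.02
#>    Weighted mode    77 0.645 0.0487  0.550   0.741  4.51e-40      1.91      1.73       2.10
#>             RAPS    77 0.687 0.0163  0.655   0.719  0.00e+00      1.99      1.92       2.05
#> Cochran Q = 78.5 (df 76, p = 0.4)
#> I2_GX = 0.802   mean F = 162.3
```

Reading the table: three palindromic variants were unresolvable and
dropped with a logged reason; IVW, median, mode and RAPS all land on the
true OR ≈ 2; the plain Egger slope is attenuated by exposure-side
measurement error (I²GX = 0.80 < 0.9 flags this), and the SIMEX row is
the corrected estimate; Cochran's Q shows no excess heterogeneity, as
expected with no pleiotropy simulated.

`runPipeline(analysisConfig(...), out_dir = "...")` runs the same
battery in both directions from file inputs and writes
`forward_results.tsv`, `reverse_results.tsv`, diagnostics, drop logs, a
rendered `report.txt` and a `manifest.json` with input checksums, every
threshold and all seeds.

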