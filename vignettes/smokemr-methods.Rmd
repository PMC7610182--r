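---
title: "Lifetime smoking exposure and two-sample Mendelian randomisation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime smoking exposure and two-sample Mendelian randomisation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokemr)
```

# The scientific problem

Smoking is far more common among people with schizophrenia and depression
than in the general population, and observational designs cannot decide
how much of that association is causal, in which direction it runs, or how
much is confounding. Two-sample Mendelian randomisation (MR) addresses
this by using genetic variants as instruments: SNP–exposure effects
$\hat\gamma_j$ (with standard error $\sigma_{\gamma j}$) come from a GWAS
of the exposure, SNP–outcome effects $\hat\Gamma_j$ (standard error
$\sigma_{\Gamma j}$) from an independent GWAS of the outcome, and under
instrument validity each ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the
causal effect $\theta$.

A complication specific to smoking is that "being a smoker" is a poor
summary of exposure. This package therefore implements a **lifetime
smoking index** that folds smoking status, duration, intensity and time
since cessation into one continuous score usable in unstratified samples,
plus the full two-sample MR machinery to run the analysis in both
directions.

# The lifetime smoking index

For a person who smoked `cpd` cigarettes a day for `dur` years and
stopped `tsc` years before assessment, the index is

$$ S = \left(1 - 0.5^{\,dur/\tau}\right)\; 0.5^{\,tsc/\tau}\;
   \ln(cpd + 1), $$

where the half-life $\tau$ (years) captures the exponentially decaying
effect of past smoking on present risk. The first factor accumulates
exposure with duration (saturating — early years matter most), the second
decays it after cessation, and the log-intensity term gives diminishing
returns in cigarettes per day. Never smokers score exactly zero; the score
is bounded above by $\ln(cpd+1)$; and it is invariant to rescaling
$(dur, tsc, \tau)$ by a common factor, so $\tau$ is genuinely a time
scale.

```{r index}
# 20 a day for 15 years, quit 17 years ago -- and a heavier, shorter,
# longer-quit history -- give the same score at tau = 18
lifetimeSmokingIndex(c(15, 13), c(17, 22), c(20, 60), tau = 18)
```

At $\tau = 18$ both reference histories evaluate to 0.694, which is the
index's empirical standard deviation in the UK Biobank population the
score was built for — so one unit of these histories is one SD of
exposure.

## Calibrating the half-life

$\tau$ is not estimable from smoking histories alone; it is calibrated
against a health outcome. `calibrateHalfLife()` scans a grid of
candidates, scores the cohort at each, fits a single-predictor logistic
regression of the outcome on the score, and picks the candidate with the
highest log-likelihood (ties go to the smaller $\tau$; a likelihood-ratio
screen warns when the outcome carries no smoking signal at all, in which
case the returned $\tau$ is arbitrary). The fit criterion had to be
chosen: we use logistic log-likelihood as the simplest defensible
single-predictor criterion, and provide a Cox partial-likelihood
alternative (`model = "cox"`) because all-cause mortality — a
time-to-event outcome — is a natural calibration target for smoking.
Former smokers whose cessation age is missing cannot be scored and are
excluded with a reported count rather than imputed.

```{r calibrate}
sim <- simulateCohort(cohortConfig(n = 20000, seed = 1))
calibrateHalfLife(sim$histories, sim$outcome$outcome,
                  grid = seq(6, 30, by = 3))
```

# From summary statistics to a harmonised dataset

`readSummaryStats()` ingests GWAS association tables across common header
dialects (`A1/A2` vs `EA/OA`, `OR` vs `BETA` with a log transform),
validates every row, and logs rejects with file line numbers.
`selectInstruments()` keeps genome-wide significant records
($p < 5\times10^{-8}$) and applies greedy clumping: visiting variants in
ascending p-value order, a variant is pruned when it lies within
10,000 kb of a retained variant on the same chromosome *and* is in LD
with it at $r^2 \ge 0.001$. The package ships no LD reference panel:
users supply a pairwise $r^2$ table, and without one the distance rule
alone decides, prominently logged as approximate.

`harmoniseData()` aligns the outcome study to the exposure study's effect
alleles: swapped labels negate the effect and reflect the allele
frequency; labels differing by strand complement are complemented first.
Palindromic variants (A/T, C/G) carry no strand information in their
labels, so they are resolved by allele-frequency agreement — and only
when the minor allele frequency is below 0.3 in both studies; otherwise
(including when either frequency is missing) they are dropped with a
recorded reason. Instruments absent from the outcome study can be rescued
by user-supplied proxies at $r^2 \ge 0.8$ with an explicit allele
mapping. Harmonisation is idempotent, invariant to consistent relabelling
of both studies, and accounts for every input variant (retained + dropped
= input).

# The estimator battery

All five estimators consume the same harmonised dataset; their point is
that they fail differently, so agreement across them is evidence the
effect is not an artefact of one pleiotropy assumption.

* **IVW** — weighted regression of $\hat\Gamma$ on $\hat\gamma$ through
  the origin, weights $1/\sigma_\Gamma^2$. The main analysis. Standard
  errors use a multiplicative random-effects model: the residual scale is
  $\max\!\left(1, \sqrt{Q/(J-1)}\right)$, so heterogeneity can widen but
  never narrow intervals; p-values use $t_{J-1}$. Fixed-effects scaling is
  available by argument.
* **MR-Egger** — the same regression with an intercept, after orienting
  all $(\hat\gamma_j, \hat\Gamma_j)$ pairs so $\hat\gamma_j \ge 0$. The
  slope is consistent under InSIDE even with directional pleiotropy; the
  intercept estimates the average direct effect and its $t_{J-2}$ test is
  the directional-pleiotropy screen.
* **Weighted median** — the inverse-variance-weighted median of the Wald
  ratios (cumulative-weight crossing of 1/2 with linear interpolation);
  consistent while valid instruments hold a majority of the weight.
  Standard errors by parametric bootstrap of $(\hat\gamma, \hat\Gamma)$.
* **Weighted mode** — the mode of the weighted normal-kernel density of
  the ratios (modified Silverman bandwidth,
  $0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$, times a configurable
  factor); consistent when the largest group of agreeing ratios is valid.
* **RAPS** — maximises the profile likelihood built from standardised
  residuals
  $t_j(\beta) = (\hat\Gamma_j - \beta\hat\gamma_j)\big/
  \sqrt{\sigma_{\Gamma j}^2 + \beta^2\sigma_{\gamma j}^2}$, which
  accounts for exposure-side measurement error (no NOME assumption and no
  weak-instrument attenuation). Options: Huber loss (tuning 1.345) and a
  jointly-estimated overdispersion component for systematic pleiotropy;
  sandwich standard errors. Numerically, the profile loss is bracketed on
  a coarse grid before local refinement, because a near-zero
  $\hat\gamma_j$ can throw one ratio far out and create spurious optima.

Diagnostics: Cochran's $Q$ about the IVW estimate; the Egger intercept;
the mean F statistic $\overline{\hat\gamma^2/\sigma_\gamma^2}$ for
instrument strength; $I^2_{GX}$ for Egger regression dilution; and
Steiger filtering, which flags a variant as wrong-direction when it
explains more variance in the outcome than in the exposure
($r^2 = 2\hat\beta^2\,\mathrm{eaf}(1-\mathrm{eaf})$ on the standardised
scale — for binary traits this is a liability-linear approximation, and
exact ties are flagged indeterminate but retained).

## SIMEX correction for Egger dilution

Measurement error in $\hat\gamma$ attenuates the Egger slope; $I^2_{GX}$
quantifies the attenuation, and values below 0.9 trigger
simulation-extrapolation in `runMR()`. Following the convention for this
correction the SIMEX regression is **unweighted**: for each
$\lambda \in \{0, 0.25, \dots, 2\}$ we add noise of variance
$\lambda\sigma_{\gamma j}^2$ to the exposure effects, average the Egger
slope over replicates, fit a quadratic in $\lambda$, and extrapolate to
$\lambda = -1$ (zero measurement error). The standard error extrapolates
the replicate-mean squared slope standard errors the same way — the
conventional shortcut to a full bootstrap of the whole procedure, whose
cost is quadratic in replicates. Degenerate extrapolations fall back to
the uncorrected estimate with a warning; grids with fewer than three
noise levels cannot support the quadratic and return the observed-noise
estimate.

A caution discovered during validation and worth stating: SIMEX has a
well-defined correction target only when the instrument effects are
bounded away from zero. With a half-normal effect distribution at low
mean F, many $\hat\gamma_j$ sit near zero and the $|\gamma|$-orientation
folding changes the zero-measurement-error estimand itself, so "full
correction" lands above the truth. Real clumped instruments (every
variant genome-wide significant) do not have this structure — their
effects are bounded away from zero yet *tightly clustered*, which is
exactly the regime that produces low $I^2_{GX}$ — and the package's
dilution tests use that regime (`gamma_mean = 0.03`,
`gamma_scale = 0.005`: mean F ≈ 175, $I^2_{GX} \approx 0.8$).

# The synthetic-data generators

`simulateSummaryStats()` draws, per variant: an allele frequency
$\mathrm{eaf} \sim U(0.1, 0.9)$; a true exposure effect
$\gamma_j = |N(\mu_\gamma, s_\gamma)|$ (oriented to the
exposure-increasing allele, as published instruments are); a direct
pleiotropic effect $\alpha_j$ under one of four regimes (none; balanced;
directional with a configurable carrier fraction; InSIDE-violating via a
configurable $\gamma$–$\alpha$ correlation); the true outcome effect
$\Gamma_j = \theta\gamma_j + \alpha_j$; and estimates with the standard
GWAS sampling approximation
$\sigma = 1/\sqrt{2n\,\mathrm{eaf}(1-\mathrm{eaf})}$ on the standardised
scale (binary-outcome effects are generated directly on the log-OR
scale). Allele labels include configurable fractions of palindromic
variants, label swaps and strand flips, so harmonisation is genuinely
exercised; the truth table records every latent value, and
`truthDataset()` rebuilds the correctly-aligned dataset for estimator
validation. Identical config and seed give byte-identical output.

Defaults emulate the study the package models: exposure GWAS
$n = 462{,}690$, outcome GWAS $n = 150{,}064$, and
$s_\gamma = 0.0146$, which yields mean F ≈ 40 — a well-powered but
realistically noisy instrument (the spread is also what makes
$I^2_{GX}$ imperfect, as observed in practice).

`simulateCohort()` draws smoking status with the never/former/current
mix 0.5389/0.3559/0.1053 — the exact proportions behind the rounded
54/36/11% split of the 462,690-person reference population (the
literature also quotes a 30%-ever figure for an overlapping sample; the
two are inconsistent and we deliberately use the GWAS-sample mix).
Assessment ages are normal (56.7, sd 8) clamped to 40–69, initiation ages
normal (17, sd 3), cigarettes/day log-normal (median 15) clamped to the
1–150 plausibility window, and cessation ages uniform between initiation
and assessment. The binary outcome is drawn from a logistic model on the
true index at $\tau_{true} = 18$; the default coefficients (intercept
−2.2, slope 1.0 per index unit) are all-cause-mortality-like — about 10%
baseline risk and an odds ratio near 2 per index SD — chosen once from
the smoking–mortality literature.

**What the generators do not emulate:** LD between instruments (variants
are exchangeable and independent), winner's-curse selection of
instruments, population stratification, sample overlap between the two
GWAS, participation/selection bias, and any real genetic architecture.
Passing tests therefore demonstrate that the *machinery* is correct under
its stated assumptions, not that those assumptions hold in any particular
real dataset.

# Validation design and problem sizes

The test suite separates two questions.

*Is the code right?* Closed-form cases, independent weighted-least-squares
and cumulative-weight-scan oracles, and invariance properties (scale
equivariance, orientation invariance, harmonisation idempotence) are
checked exactly. Estimator recovery is then verified in a
**strong-instrument validation scenario** ($s_\gamma = 0.074$, mean F ≈
1000): there the no-measurement-error assumptions hold and all five
estimators must hit $\theta = \ln 2$ within Monte-Carlo error (500
replicates, J = 100), with IVW 95% intervals covering in 93–97% of 1000
replicates. At the realistic default strength (mean F ≈ 40) IVW and Egger
carry their *known* finite-sample attenuations (of order $1/F$ and
$1 - I^2_{GX}$); testing unbiasedness there would measure those
properties, not implementation correctness.

*Does the method behave as advertised?* Operating characteristics are
checked in the realistic regimes: type-I error under balanced pleiotropy
at $\theta = 0$ (2000 replicates — note the multiplicative scale floor
makes these tests nominal-to-conservative by design, so the check is
one-sided against anti-conservatism); weighted-median robustness with 30%
invalid instruments against IVW's bias (200 replicates); SIMEX against
naive Egger in the clustered low-$I^2_{GX}$ regime (200 replicates); and
half-life recovery at $N = 20{,}000$ across 10 seeds on the grid
$\{6, 9, \dots, 30\}$, within one grid step. These problem sizes keep the
whole suite under a minute while leaving Monte-Carlo error well below the
tolerances tested.

# Known limitations

* Clumping and proxy search operate on user-supplied LD information only;
  without it, distance-only pruning is an approximation and is logged as
  such.
* Steiger $r^2$ for binary traits uses the standardised-scale
  approximation $2\beta^2\mathrm{eaf}(1-\mathrm{eaf})$, not a full
  liability-scale conversion with case fraction.
* The SIMEX standard error is the variance-extrapolation approximation,
  not a full procedure bootstrap.
* RAPS overdispersion with the Huber loss solves moment equations whose
  normal-theory constant is computed for the standardised residuals;
  heavy contamination beyond what the Huber $\psi$ absorbs will bias the
  overdispersion estimate.
* Multivariable MR, correlated-instrument (LD-aware) IVW, and
  contamination-mixture estimators are out of scope.
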