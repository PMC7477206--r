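---
title: "Modelling cerebrovascular risk, frontoparietal integrity and executive function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebrovascular risk, frontoparietal integrity and executive function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrsem)
```

## The scientific problem

Cerebrovascular risk (CVR) factors — hypertension, hypercholesterolaemia,
diabetes, smoking, central adiposity and APOE ε4 carriage — are suspected to
erode cognition in *healthy* ageing, well before any dementia diagnosis, by
damaging the grey and white matter of the frontoparietal control network
that underlies executive function. Testing that mechanistic chain requires
linking, in one model: a per-person risk burden, white-matter
hyperintensity (WMH) load, latent summaries of frontoparietal grey-matter
volume and superior-longitudinal-fasciculus (SLF) microstructure
(NODDI ICVF and OD), and a latent executive-function (EF) score built from
reaction-time and pairs-matching performance.

`cvrsem` implements that analysis chain end to end: rule-based CVR scoring,
trial-level cognitive preprocessing and robust normalisation, a
latent-variable structural equation modelling (SEM) engine with
full-information maximum likelihood (FIML), model-free sliding-window
blood-pressure curves, correlation/regression inference, bootstrap
mediation — and a synthetic cohort generator with a known ground truth so
that every stage can be validated without access-restricted data.

## The cerebrovascular risk score

The score is the sum of seven components (range 0–9):

| component | rule | points |
|---|---|---|
| measured hypertension | mean SBP ≥ 140 **and** mean DBP ≥ 90 mmHg (mean of two readings) | 0/1 |
| antihypertensive use | flag | 0/1 |
| cholesterol-lowering use | flag | 0/1 |
| diagnosed diabetes | flag | 0/1 |
| waist-to-hip ratio | ≥ 0.90 (men) / ≥ 0.85 (women) | 0/1 |
| smoking | pack-years in [10, 50] → 1; > 50 → 2 | 0–2 |
| APOE | one point per ε4 allele | 0–2 |

Design choices a user should know about:

* **All thresholds are inclusive** and collected in `cvr_thresholds()`. The
  hypertension rule requires both readings at threshold; the WHO cut-offs
  0.90/0.85 are used for the waist-to-hip ratio (the WHO guideline is cited in
  the hypertension literature without numbers).
* **Pack-years** are `(cigarettes/day ÷ 20) × (stop age − start age)`, with
  the stop age replaced by the age at scan for current smokers. Ending the
  exposure window at the quit age *is* the adjustment applied for people who
  gave up smoking; no additional multiplier is used. `smoking_points()`
  accepts pre-adjusted pack-years directly, which is the hook for any other
  convention.
* **Measured hypertension and antihypertensive use can both score** for the
  same participant (sum semantics); the two components index different
  evidence (current pressure vs established diagnosis).
* **Missing components score 0 and are flagged** (`n_missing_components`),
  the usual sum-score convention; `cvr_score(..., na_action = "propagate")`
  yields `NA` totals instead.

## Preprocessing

Reaction-time trials outside the inclusive [50, 2000] ms window are removed
(anticipations; responses after stimulus offset) before averaging. Total WMH
volume is cube-root transformed. Every model variable is then median/MAD
normalised, `(x − median) / (1.4826 · MAD)`; the 1.4826 constant makes the
scale estimate an SD under normality and can be set to 1. Because the raw
cognitive scores and orientation dispersion are "larger = worse",
`prepare_analysis_table()` negates `rt`, `pairs` and `od` by default so that
every latent loading and the GM→EF / WM→EF paths are positive; `flip =
FALSE` keeps the recorded orientation. Imaging phenotypes can be
residualised against head-size/scan-date confounds with
`residualize_confounds()` (least squares with an intercept); the confound
set is the caller's choice.

The pairs-matching error count is used as recorded (no trial-level filter is
defined for it).

## The structural model

`fp_sem_spec()` builds the default model: observed age, CVR score and WMH
load; latent grey-matter volume (`gm`: six regional volumes), white-matter
integrity (`wm`: ICVF and OD) and executive function (`ef`: reaction-time
and pairs scores). Directed paths run age/CVR → WMH, age/CVR/WMH → GM and
WM, and GM/WM → EF; age and CVR covary. There are deliberately **no direct
age/CVR/WMH → EF paths**: the model encodes full mediation through network
integrity, which is what makes the 4-df nested comparisons meaningful.
Correlated indicator residuals are configuration, not search — the defaults
(`ag`–`prc`, `sfg`–`fp`) live among the GM volumes, reflecting shared
membership of other structural covariance networks. Modification-index
discovery is out of scope.

The engine uses the RAM parameterisation. With `A` holding directed edges
(loadings and paths) and `S` symmetric (residual (co)variances), the implied
covariance of the observed vector is

\[
\Sigma(\theta) = F (I - A)^{-1} S (I - A)^{-\top} F^\top ,
\]

and maximum likelihood minimises
\(F_{ML} = \log|\Sigma| + \mathrm{tr}(S_n \Sigma^{-1}) - \log|S_n| - p\).

Numerical choices:

* **Identification** is unit-loading (marker) per latent; the standardised
  solution (every edge rescaled by implied source/target SDs) is invariant
  to that convention, which is why all published-scale comparisons are made
  on `standardized_solution` output.
* **Likelihood convention**: the default `"wishart"` uses the unbiased
  sample covariance and reports `chisq = (n−1)·F`; `"normal"` uses the
  divisor-`n` covariance and multiplier `n` and coincides exactly with the
  FIML objective on complete data (this is the pairing used by the
  equality tests).
* **Optimisation** is quasi-Newton (`nlminb`) with analytic RAM gradients,
  followed by a Newton polish that drives the gradient norm to near machine
  precision; non-convergence triggers up to 3 restarts from
  deterministically perturbed starts (no RNG inside the fitter). The
  convergence flag requires a relative gradient norm below `1e-5`; in
  practice polished fits sit near `1e-9` or better.
* **Heywood cases**: variance parameters are bounded below at `1e-6` and a
  boundary estimate triggers a warning — never a silent absolute value.
* **FIML** groups rows by missingness pattern, maximises the casewise
  Gaussian likelihood over each row's observed subset with saturated means
  (estimated jointly), and assumes missing-at-random. Its model chi-square
  uses the saturated log-likelihood from an EM fit of the unrestricted
  Gaussian model; the baseline (independence) model is fitted per variable.
* **Fit indices**: CFI and TLI are computed against the independence model
  on the same variables and cases and clipped to [0, 1] for reporting;
  RMSEA is undefined (NA) for saturated models.

`constrain_variable_paths()` fixes every free structural path touching a
variable to zero (measurement loadings and covariances are kept), which for
either GM or WM removes exactly 4 paths — hence the 4-df chi-square
difference tests produced by `chi_square_difference()`.

## Window curves, association and mediation

`sliding_window_curve()` slides a quantile window holding 10% of
participants along the SBP distribution in 1-percentile steps (91 windows at
the defaults). The window *width* is prescribed by the design being
replicated; the 1-percentile step is this package's choice of a dense slide.
Each window reports median SBP, mean outcome, and SD/√count as the
standard error. `gaussian_smooth()` interprets "kernel of 10" as a Gaussian
SD of 10 window-index units with edge renormalisation (weights always sum to
1); an FWHM convention can be emulated by rescaling the kernel argument.
`fixed_bin_curve()` uses 10 fixed 16-mmHg bins anchored at `min(x)` floored
to a multiple of the width; empty bins are flagged, never interpolated.
`age_quantile_residuals()` removes each age-decile's mean from a variable
(10 bins by default — the bin count is unstated in the published design and
configurable), with ties broken by original row order.

`pearson_ci()` uses the Fisher-z closed form for intervals (the published analysis's CI
construction is unstated; the printed intervals there are slightly wider than the
closed form implies, and that discrepancy is noted, not reproduced).
`fisher_rz_compare()` implements the two-sample r-to-z test.
`fit_regression()` is ordinary least squares with standardised betas from
z-scored refits and VIF diagnostics. Note the published analysis reports the same
whole-sample comparison as z = −3.87 in one place and −3.84 in another;
nothing in this package resolves that.

`mediate()` is single-mediator linear mediation with case-resampling
percentile bootstrap intervals (10,000 draws by default; a seed is
mandatory). On complete data `c_total = c_direct + a·b` holds exactly.

## The synthetic cohort generator

`generate_cohort()` emulates the cross-sectional imaging cohort the analysis
assumes:

* **Age** is a truncated normal on [44, 73] whose *pre-truncation*
  parameters are solved numerically at generation time so the truncated
  distribution has mean 62 and SD 7 (plain truncation of N(62, 7²) would
  undershoot both).
* **Prevalences** (diabetes 5%, cholesterol medication 21%, antihypertensive
  medication 22%, never-smokers 78%) are logistic in standardised age (and,
  for antihypertensives, in underlying SBP); the intercepts are solved by
  root-finding against the realised covariates so the marginals hit their
  targets up to binomial noise. The age slopes were calibrated once so the
  rule-based score's age correlation is ≈ 0.25, the exogenous Age↔CVR
  covariance of the ground truth.
* **The CVR score is computed, not drawn**: raw risk-factor fields are
  generated and passed through `score_cohort()`, so the scoring rules sit
  inside the generative loop and the "CVR" entering the structural equations
  is exactly the standardised rule-based score.
* **Structural variables** (WMH, GM, WM, EF) are built on the standardised
  scale from the published path coefficients, with residual variances solved
  so every variable has unit variance. The two WMH→network paths are not
  printed in the published results; the defaults −0.10 (GM) and −0.15 (WM) are
  this package's assumption, chosen so the CVR→WM path would strengthen if
  the WMH→WM path were removed.
* **Raw mappings invert under preprocessing**: WMH is generated on the cube
  scale of a Gaussian (so the cube root normalises it); volumes and NODDI
  indicators are affine in their standardised scores (raw OD decreasing in
  integrity); the participant's mean reaction time is affine in the RT score
  and the 12 log-normal trials are renormalised so the *filtered* trial mean
  reproduces it exactly, with ~2% out-of-window trials injected afterwards.
  The measurement model therefore holds exactly on the analysis scale for
  every indicator except the pairs-matching errors, which are over-dispersed
  counts obtained by quantile transform — deliberately discrete, which
  mildly attenuates that one loading (the attenuation scales every
  covariance of the count by a common factor, so the data remain an exact
  factor model with a slightly smaller pairs loading).
* **The SBP–EF link** enters the EF residual: linear in SBP for unmedicated
  participants and rectified above 140 mmHg (plateau below) for the
  medicated. The contribution is orthogonalised against age before being
  added, so the modelled structural paths stay exact; a small residual
  correlation with the CVR score (through the hypertension component)
  remains and is second-order (≲ 0.001 on the path scale).
* **Missingness** (`inject_missingness()`) is missing-at-random with the
  cell probability increasing in observed age, applied to the imaging and
  cognitive columns only.

What the generator does **not** emulate: selection effects of a volunteer
imaging cohort, measurement-device changes, site/batch structure,
non-Gaussian tails of imaging phenotypes, genetic structure beyond APOE, or
longitudinal dynamics. Passing tests therefore demonstrate the *software*
recovers what it injects under the assumed model — not that the model is
true of any real population.

## Validation design and known limitations

The test suite checks each operation against an independent oracle
(closed-form OLS/normal equations, exhaustive window enumeration, worked
fit-index examples) and the whole chain by generate-and-refit recovery.
Problem sizes in the suite were chosen to keep the default run fast:
cohorts of 150–22,059 for marginals, 20,000 for recovery (5 replicates),
100,000 for the law-of-large-numbers check of the implied covariance.

A limitation worth stating plainly: the EF latent is measured by only two
indicators with standardised loadings 0.49 and 0.25, so at n = 20,000 the
model-based standard errors of the standardised WM→EF path and EF→RT
loading are ≈ 0.016 (as `fit_sem(..., se = TRUE)` reports). A ±0.02
recovery band is therefore only ~1.2σ for those parameters, and individual
replicates will miss it with appreciable probability even though estimates
are unbiased and the fitter is at the information limit. The CVR→WMH path
(σ ≈ 0.006) recovers far inside the band. The recovery test in the suite
asserts the strict band and documents this behaviour.

Other limitations: no robust/WLSMV estimation, no ordinal indicators, no
multi-group models, no modification indices; the sliding-window curve is
descriptive (no changepoint inference for the ~140 mmHg plateau); mediation
is single-mediator linear.
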