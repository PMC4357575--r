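---
title: "Comparing deficit-accumulation and phenotypic frailty: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing deficit-accumulation and phenotypic frailty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtycompare)
```

## The two instruments

The package compares two operationalizations of frailty in
community-dwelling women aged 55 and over.

**Phenotypic frailty (PF).** Five criteria — slowness/weakness,
exhaustion, low physical activity, unintentional weight loss — scored from
survey items rather than performance measures: the ten SF-36
physical-functioning items (0, 50 or 100 points each, averaged), the four
SF-36 vitality items (0–100 in steps of 25, reverse-coded for the
positively worded "energy" and "full of life" items; the middle response
"some of the time" scores 50 by linear interpolation between the published
75 and 25), days walked at least 20 minutes in the past 30, and a binary
10-lb unintentional weight-loss flag. A participant whose component falls
in the lowest quartile of the sample distribution earns points — 2 for
slowness/weakness (it stands in for two of the original phenotype's five
criteria), 1 for each of the others — and the total maps 0 → robust,
1–2 → pre-frail, 3–5 → frail. The lowest-quartile boundary is *inclusive*
(score ≤ Q1): ties at the cut must score consistently, and a tie sitting
exactly at the 25th percentile is "in" the lowest quarter on any natural
reading. Quartiles are the type-7 (linear interpolation) sample quantiles;
the variant is an argument of `compute_quartile_cuts()` so other
conventions are reproducible, and cuts can be serialized
(`write_quartile_cuts()`) for out-of-sample scoring.

**Frailty index (FI).** Thirty-four deficits — 6 symptoms/signs, 15
comorbidities, 12 activities of daily living, 1 healthcare-utilization
item — each coded into [0, 1] by an ordered level→value map, summed and
divided by 34. The denominator stays 34 even when items were imputed
upstream (the instrument divides by the total item count); a
`denominator = "answered"` switch supports FI literatures that divide by
the answered count. The codebook is data, not code: the shipped YAML file
reproduces the domain structure and the published polychotomous coding
pattern (evenly spaced values; e.g. "feels full of life" codes
0/0.25/0.5/0.75/1 from "all of the time" to "none of the time"), but the
item wording is a synthetic structural stand-in, because the original
34-item survey codebook is not publicly deposited. A verbatim codebook
drops in through `read_codebook()` without touching any scoring code.

## Putting the instruments on a common footing

Continuous FI and categorical PF are not directly comparable; three
strategies align them.

**Strategy 1 — per-one-fifth increments.** PF effects are reported per 1
point of the 0–5 score. FI effects are reported per one fifth of the
*observed* range, `(max − min)/5`; binning the FI at successive multiples
of the rounded increment also yields a 0–5 level for agreement statistics.
Two boundary conventions are deliberate, and chosen because they make the
published cutpoints attainable where the source is silent: bins are
left-open/right-closed, and level 0 is reserved for an index of exactly
zero (a participant with no deficits at all), which is the only reading
under which the lowest bin can hold a handful of deficit-free participants
rather than a fifth of the cohort.

**Strategy 2 — density-overlap trichotomization.** The FI is split at the
crossings of Gaussian-kernel density estimates of its distribution within
the three PF categories: cut 1 where the robust and pre-frail densities
cross between their means, cut 2 likewise for pre-frail vs frail.
Numerical choices: rule-of-thumb ("nrd0") bandwidth, 512-point grid over
[0, 1], linear interpolation of the crossing between grid points; with
several crossings in the inter-mean interval the one nearest the midpoint
of the means is used, and with none the midpoint itself is returned with a
warning (two identical distributions have no informative crossing). The
crossing-point reading of "overlap in the density distribution" is one
concrete interpretation and is isolated in `strategy2_cutpoints()`, so an
alternative (ROC-optimal, tertiles) can replace it without touching the
rest of the pipeline.

**Strategy 3 — predicted fall risk.** A multivariable logistic model of
third-year falls on the FI (adjusted for age, smoking, drinking, BMI,
education and baseline falls) yields in-sample predicted probabilities,
grouped at 0.27 and 0.50 — published estimates of the annual fall
probability in the elderly generally, and among those with a prior fall or
gait/balance abnormality. Intervals are left-closed/right-open, so a
predicted probability of exactly 0.50 is high risk. Probabilities are
in-sample (no cross-validation is described for the original analysis);
out-of-sample scoring can reuse the fitted model via `predict` on new
data.

## Outcome models and reporting scales

Falls (binarized to ≥ 1 fall in follow-up year 3) and death use logistic
regression; incident fracture uses Cox proportional hazards on
time-to-first-fracture with administrative censoring at 3 years and
censoring at death (dates exist only for fractures, so this is the minimal
consistent survival frame; the interaction of death and fracture follow-up
is a recorded choice, not a claim about the source data). Ties use the
Efron partial likelihood. Each model comes age-adjusted and fully
adjusted; the adjustment sets (falls: age, smoking, drinking, BMI,
education, baseline falls; fractures: age, smoking, drinking, prior
fracture, family history, BMI, education; death: age, smoking, drinking,
BMI, education) live in `outcome_covariates()`. Drinking (0, <7, 7–13,
≥14 drinks/week) and baseline falls (0, 1, ≥2) enter as ordinal integers —
a config-visible coding that can be swapped for dummies. Effects rescale
exactly: the OR/HR per increment Δ is `exp(βΔ)`, so
`effect(Δ) = effect(1)^Δ`, and Wald 95% intervals rescale with it.
Proportional hazards are checked with the Grambsch–Therneau scaled
Schoenfeld residual test (event-time rank transform) per covariate and
globally.

## Discrimination, calibration, agreement

These statistics are implemented from first principles (the comparison
machinery is the point of the package), with established libraries as
independent cross-checks in the tests, never as the implementation:

* AUC by the Mann–Whitney rank statistic with midrank ties; variance and
  paired covariance from the DeLong placement components; the paired
  contrast `z = ΔAUC / sqrt(v_a + v_b − 2c)` with a two-sided normal
  p-value. Identical score vectors short-circuit to p = 1 exactly.
* Harrell's c for censored data: usable pairs are those orderable under
  censoring (tied event times with both events are excluded), score ties
  count one half. With no censoring and a binary "time" equal to the
  inverted event label, c reduces to the AUC — a cross-oracle identity the
  tests exercise. No analytic comparison of correlated c-indices is in
  common use, so the contrast is a paired bootstrap (default 1000
  resamples, seeded, resample count exposed).
* Hosmer–Lemeshow over deciles of predicted risk,
  `Σ (O−E)² / (E(1−E/n_g))` on g − 2 degrees of freedom; duplicate
  quantile breaks collapse, and groups whose denominator vanishes merge
  into a neighbour with a warning.
* Spearman agreement as Pearson correlation of midranks (the tie-corrected
  formula) with a Fisher-transform interval, SE `1/sqrt(n−3)`.

## The synthetic cohort generator

No participant-level data are deposited for the cohort this package
models, so the generator is a first-class module: it defines the study
conditions under which every statistical claim is tested.

A single latent frailty trait `Z = 0.5·(age − 70)/10 + N(0, 1)` drives
everything: deficit items through monotone links (item severity
`plogis(a_i + 0.55·Z + N(0, 0.8))` snapped to the nearest codebook level,
with per-item intercepts spread across items and a global shift of 0.32),
and the phenotypic items through noisy monotone transforms of −Z. One
factor shared by both instruments is the simplest mechanism that produces
their observed correlation, with the component noise as the tuning knob.
Two structural details matter. First, each 0–100 phenotypic component has
a person-level random effect (sd 0.75) *in addition to* per-item noise,
because per-item noise averages out over a 10-item component; without the
shared term the four criteria become near-deterministic functions of Z and
the frail category balloons far beyond a realistic share. Second, baseline
falls load on Z (slope 0.9), as they do in real cohorts where prior falls
track frailty; this also keeps the strategy-3 grouping — which mixes
baseline falls into the predicted risk — in agreement with the phenotype.

Outcomes are generated from the *realized* FI computed from the generated
deficits, not from Z: falls and death by logistic models, fracture times
exponential given covariates (the simplest proportional-hazards-true
process), with true per-increment effects OR 1.4 (falls), OR 1.8 (death),
HR 1.25 (fracture) at the reference increment 0.144. This makes the
downstream fits correctly specified, so parameter recovery is well-posed.
Intercepts are calibrated by root-finding so the *expected* marginal rates
equal the targets 0.32 / 0.064 / 0.027; realized rates then differ only by
binomial noise. All randomness flows from one seed through a local RNG
scope; the caller's random state is untouched, and the same (config, seed)
reproduces the table bit-exactly.

Under the defaults (n = 4000, two-thirds aged 65+), the generated cohort
shows FI mean ≈ 0.24, SD ≈ 0.137, category frequencies ≈ 47/31/21 with the
robust > pre-frail > frail ordering, PF–FI Spearman ≈ 0.66/0.65/0.52
across the three strategies, and strategy-2 cutpoints near 0.20/0.32.

**What passing tests do and do not show.** The generator emulates
marginal distributions, a plausible dependence structure and known-truth
effects; it does not emulate informative non-response, recall error in
self-reported outcomes, multi-site sampling, or real item wording. Tests
passing against it demonstrate that the *statistical machinery* is correct
under the stated conditions — not that any substantive estimate from a
real cohort is reproduced.

## Missing data

Variables missing below 10% are filled with the within-group median
(numeric) or mode (categorical); the source analysis used group
median/mean imputation at this threshold without specifying which applied
per variable type, so median-for-numeric/mode-for-categorical is the
package default, with mean as an option. At or above 10% the package fills
each missing cell by a seeded draw from the variable's observed
within-group empirical distribution — a documented single-imputation
simplification of the original ten multiple imputations, acceptable here
because imputation uncertainty is not propagated into any reported
quantity; the policy object keeps the procedure pluggable. The group key
defaults to the full sample and can be any column (e.g. the PF category
once scored). Outcome columns are never imputed — outcome models are
complete-case. Imputation never alters observed cells, logs every fill,
and is idempotent on its own output.

## Problem sizes and numerical choices

The simulation-based test blocks use sizes chosen to give each check
adequate power while keeping the suite quick to run routinely: 2000
replicates at n = 200 for the DeLong type-I error (the [0.03, 0.07]
acceptance band is ±4 binomial SDs around 0.05), 200 replicates at
n = 4000 for coverage of the generator truth, 500 replicates at n = 1000
for Hosmer–Lemeshow uniformity, and n = 2000 per group for
density-crossing recovery within ±0.02 of the closed-form two-Normal
intersection. GLM convergence follows `stats::glm` defaults with an
explicit non-convergence/separation guard (|β| > 15 triggers an error
suggesting a penalised fallback); Cox fits drop constant covariates with a
warning rather than failing.

## Known limitations

* The shipped codebook is structurally faithful but not the verbatim
  instrument; FI values on real data require the true codebook.
* Death and fracture are modelled without competing risks; falls are
  binarized (fall counts are kept in the data model but not modelled).
* Strategy-2 cutpoints inherit kernel-density bias at crossings of similar
  densities; with near-identical group distributions the midpoint fallback
  is a convention, not an estimate.
* AUCs and c-indices are in-sample, matching the original analysis; an
  optimism-corrected comparison would need cross-validation on top.
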