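---
title: "Modeling mortality under dynamically expanding disease portfolios"
author: "coxportfolio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mortality under dynamically expanding disease portfolios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxportfolio)
```

## The problem

Patients diagnosed with chronic heart disease (HD) rarely stay
single-diseased: over the years after diagnosis they accumulate further
chronic conditions — cancer, COPD, dementia, diabetes, and so on. The set
of chronic diseases a patient holds at a given moment is their *disease
portfolio*, and it expands over follow-up. Analyses that freeze
comorbidity at baseline, or that add up per-disease hazard ratios as if
diseases acted independently, misstate the mortality risk of multimorbid
patients: disease effects interact, sometimes strongly, and the
interactions reach across biological and socioeconomic variables.

`coxportfolio` implements the full modeling pipeline for this problem on
counting-process survival data:

1. **Encoding** person/event registries into start–stop risk intervals on
   the years-since-HD timescale, with piecewise-constant disease
   indicators.
2. **Fitting** the extended Cox model
   \(h_i(t) = h_0(t)\exp\{\sum_j \beta_j X_{ij}(t)\}\),
   where \(h_0(t)\) is the unspecified baseline hazard of a male patient
   with no education and no disease beyond HD, at mean age and calendar
   time.
3. **Discovering interactions** among the 14 disease indicators and the
   intrinsic variables (sex, age, educational attainment, calendar time)
   by a hierarchical forward–backward likelihood-ratio search, and
   independently by stability selection with L1-penalized Cox models.
4. **Summarizing** fitted models as portfolio-level hazard ratios,
   aggregated on the log-hazard scale with occurrence weights, as
   additive-vs-interaction multipliers, sex contrasts, and conditional
   single-disease effects.
5. **Translating** log-hazard effects to the absolute-risk scale through
   scenario curves built on the Breslow baseline.

Because the registry data such analyses run on are protected, the package
ships a synthetic registry generator with known ground truth; every claim
the test suite makes is checked against that truth or against independent
oracles (enumerated partial likelihoods, closed forms, brute-force
recomputation).

## The model and its encoding

Time zero is the HD diagnosis. Each subject becomes a sequence of
left-open, right-closed risk intervals, one per inter-diagnosis segment; a
subject is at risk at time *t* in an interval (start, stop] iff
start \< *t* ≤ stop, which handles delayed entry naturally. Disease
indicators are 0 before the diagnosis date and 1 from it onward; a
diagnosis dated on or before the HD date is on from *t* = 0. Two
conventions avoid degenerate rows:

* A diagnosis on the final day of follow-up cannot open a zero-length
  interval; its indicator is set on the terminal interval instead.
* Event times are whole days, so tied event times are common; the partial
  likelihood uses the Efron tie correction throughout the unpenalized
  fits.

Age and calendar time are fixed at HD diagnosis and mean-centered over
the encoded cohort; their squared and cubic terms give the baseline
flexibility in both dimensions. We read the time-fixed choice for age
from the same convention used for calendar time; attained-age
alternatives would change the baseline's meaning, not the machinery.
Education enters as a six-level factor (none, short, medium, long,
missing, missing before 1920) with "none" as reference; missingness is an
ordinary level, not an exclusion.

Estimation delegates the partial-likelihood maximization to the
`survival` package's counting-process engine (the same computation as
`coxph(ties = "efron")`, called without the model-frame overhead, which
matters when selection fits hundreds of candidate models). Aliased
columns are reported, never silently dropped; coefficients beyond ±20 are
flagged as non-converged (monotone likelihood). Proportional-hazards
diagnostics use scaled Schoenfeld residuals (`cox.zph`, identity
transform); where the assumption fails, coefficients read as
follow-up-averaged effects, and the package reports rather than remodels
this.

## Terms, hierarchy, and the interaction search

A model is a set of *terms*, each a set of variable labels; the set is
always hierarchically closed (any 5-way interaction brings along its
4-, 3-, and 2-way components and main effects). Interactions use only the
linear component of numeric variables; squared/cubic labels are
main-effects-only. A term containing education expands to five design
columns and is added or removed as a block, with likelihood-ratio degrees
of freedom equal to the expanded column count.

The forward–backward search starts from all main effects and proceeds by
interaction order *k* = 2, …, *M* (default 6):

* **Forward.** The candidates are the k-sets of variables not yet in the
  model with at least one (k−1)-subset present. With n_c candidates the
  per-test cutoff is α/n_c (Bonferroni; α = 0.001 throughout), with n_c
  frozen at the level's first enumeration. In the default relaxed variant
  all candidates are tested once against the level's starting model,
  ordered by p-value, then swept in that order, re-testing against the
  *current* model and adding immediately when the cutoff is cleared;
  discarded terms are re-offered once by plain greedy forward selection
  before cleanup. The diseases-only variant (DIO) restricts candidates to
  disease indicators and never relaxes.
* **Backward.** At each level, terms added on that level's path are
  cleaned up at level α, removing one at a time the least significant
  term that has no retained superset; main effects are never removed.
  (The scope of this cleanup is configurable to all removable terms.)
* The search stops early at the first order where nothing is added.

Every intermediate model is validated for hierarchical closure, and the
selection emits a replayable trace — applying its added/removed actions
to the starting model reproduces the final model exactly, which the tests
assert.

## Stability selection

The alternative selector draws, per subsample, 10 random variables and
half the subjects, builds the design of *all* interactions of the drawn
variables up to order 5, and fits an L1-penalized Cox path on 30
log-spaced penalties from \(\lambda_{max}\) down to
\(0.01\lambda_{max}\). A term counts as selected when any of its columns
is nonzero on the path; its frequency is selected/eligible, where
eligibility requires all the term's variables in the draw; terms at
frequency ≥ 0.9 are refit unpenalized with hierarchical closure and
backward-reduced at α.

Two numerical choices deserve explanation:

* **Path truncation.** On designs of this width (637 terms from 10
  variables, more when education expands) the un-truncated union over the
  full path saturates — essentially every eligible term goes active
  somewhere before \(0.01\lambda_{max}\), making all frequencies ≈ 1 and
  the threshold useless. The path is therefore truncated once more than
  `max_active` (default 10) columns are active, in the spirit of the
  q-capped versions of stability selection; frequencies then separate
  planted signal (≈ 1) from noise (≈ 0) cleanly.
* **Compiled path.** General-purpose penalized-Cox software handles
  (start, stop] data through a slow interpreted path, far too slow for
  hundreds of subsamples; the package implements the penalized path in
  compiled code (IRLS on the Breslow partial likelihood with a cached
  risk-set structure, cyclic coordinate descent inside). The
  implementation is validated in the test suite against `glmnet` on
  start-stop fixtures: identical \(\lambda_{max}\), identical supports,
  coefficients agreeing to ~1%. Breslow ties are standard for penalized
  screening; all unpenalized inference uses Efron.

Whether subjects (in addition to variables) are subsampled is a free
design choice; classic stability selection subsamples observations, so
the default draws half the subjects and `subject_fraction = 1` disables
it.

## Portfolio effects and aggregation

The effect of portfolio *P* for a given sex and education is the linear
predictor with *P*'s diseases on minus the predictor with none, age and
calendar at their centered zeros — a linear contrast, so its standard
error comes from the coefficient covariance, with 99.9% intervals by
default. Per-portfolio estimates are aggregated over education within sex
as weighted means on the log-hazard scale, the weights being counts of
individuals observed with exactly that portfolio at some time (each
distinct state a person ever holds counts them once); portfolios with
fewer than 10 individuals are excluded from ranked tables. The
additive-vs-interaction multiplier exponentiates the weighted mean
difference between the interaction model's and the additive model's
log-effects by portfolio size (size counts HD, so [CAN, COPD] has size
3). Sex contrasts and conditional single-disease effects are the same
contrast machinery pointed at different pairs of covariate profiles.

## Scenarios and absolute risk

A scenario is a hypothetical patient whose portfolio expands at fixed
times. Expansion times can be supplied or estimated from the cohort by
gamma regressions (log link): the time of the j-th post-HD expansion is
regressed on indicators of which diseases form a patient's first j
diagnoses, and the scenario's j-th time is the fitted mean at its own
first j diagnoses. Only the fitted mean is consumed, so the gamma shape
is profiled out by the GLM fit. The absolute risk combines the Breslow
baseline (reference: male, no education, no diseases, mean age/calendar)
with the scenario's piecewise-constant linear predictor:
\(F(t) = 1 - \exp\{-\sum_{t_e \le t} d\Lambda_0(t_e)\,e^{\eta(t_e)}\}\).
An expansion at τ affects event times strictly after τ. Scenario curves
illustrate the fitted model; since their expansion times condition on
future events they are not prognostic forecasts, and the returned object
says so.

## The synthetic registry generator

The generator is the package's ground truth. Per subject it draws sex,
education, age at HD (normal, truncated at 18), and an HD date uniform in
the calendar window; disease onsets are independent exponential clocks
(optionally portfolio-dependent through a multiplier map); each disease
is pre-existing at HD with configurable probability, which reproduces the
gap between prevalence at *t* = 0 and lifetime prevalence seen in real
trajectories; death comes from a piecewise-constant baseline hazard
scaled by exp(linear predictor) under a hierarchically closed set of true
coefficients, simulated exactly by inversion between portfolio-change
points; censoring is the minimum of an emigration clock and the
administrative end of observation. All times are rounded to whole days.
Defaults mirror the registry setting the analysis is designed for: 14
diseases, diagnosis window 1995–2016, male fraction 0.53, age 70 ± 13,
six-level education with small missingness shares, and a baseline rate
(0.08/yr) chosen so that a majority of subjects die within the
observation window. Where a study value existed it was adopted;
remaining rates (onset 0.03/yr per disease, emigration 0.005/yr,
pre-existing probability 0.35) were set once to values realistic for
chronic-disease accrual in an elderly HD cohort.

What the generator does *not* emulate: correlated onset processes,
diagnosis-pattern artifacts of algorithmic coding, non-proportional
effects, or realistic demography. Passing tests therefore demonstrate
that the machinery recovers known structure under the model's own
assumptions — not that those assumptions hold in any particular registry.

## Validation design and problem sizes

The suite checks every layer against an independent route: enumerated
partial likelihoods maximized by brute force (≤ 8 subjects), closed-form
survival and risk quantities, Nelson–Aalen consistency of the Breslow
baseline, brute-force recomputation of candidate enumeration and of
weighted aggregations, `glmnet` agreement for the penalized path, and
simulation studies with planted coefficients. The simulation studies use
n = 20,000 with 20 seeded replicates for parameter recovery and
multiplier direction, n = 5,000 (planted) and n = 2,000 (null) with 20
replicates for selection structure recovery and family-wise error,
200 subsamples for the scaled stability run, and 200 replicates of
n = 2,000 for the size of the likelihood-ratio test; these sizes give
each check sampling error well below its decision margin while keeping
the full suite runnable on a laptop.

## Known limitations

* Effects are follow-up-averaged when proportionality fails; the package
  diagnoses but does not model time-varying coefficients, frailty, or
  stratified baselines.
* The interaction search is greedy; it controls false discovery through
  Bonferroni cutoffs but does not guarantee a globally optimal model.
* Conditional-independence onset clocks in the generator understate the
  clustering of real comorbidity onsets.
* All contrasts are associational; nothing here supports causal or
  mediation claims.
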