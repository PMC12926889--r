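---
title: "Methods: trial-based cost-effectiveness analysis of depression screening feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The evaluation problem

`trialcea` implements the health-economic evaluation pipeline of a
three-arm, multicentre randomised trial of feedback interventions after
depression screening in primary care. Adults screening at least moderately
depressed (PHQ-9 total of 10 or higher) were randomised 1:1:1 to no
feedback, feedback to the general practitioner (GP), or feedback to both
GP and patient, with assessments at baseline and 1, 6 and 12 months. The
evaluation asks whether the feedback interventions are cost-effective from
a societal perspective over one year, using quality-adjusted life years
(QALYs) from the EQ-5D-5L as the effect measure, with sensitivity analyses
from the healthcare payer perspective, on complete cases only, and using
depression-free days (DFDs) derived from the PHQ-9.

The original participant-level data are not publicly deposited, so the
package ships a synthetic-data module that reproduces the *structure* of
the trial — sample sizes, instrument distributions, clustering, cost
skewness and the missingness mechanism — and every analysis stage is
implemented and validated against that synthetic test bed. All reported
numbers in this repository are therefore computed on synthetic data with
null intervention effects by default; they exercise and validate the
machinery rather than reproduce the original estimates.

## Instruments and effect measures

**EQ-5D-5L.** Health states are five-digit codes over five dimensions
(mobility, self-care, usual activities, pain/discomfort,
anxiety/depression), each on levels 1–5, giving $5^5 = 3125$ states. A
value set maps states to a utility index via additive level decrements:
$u(s) = 1 - \sum_d \delta_{d,\ell_d(s)}$. The shipped value set is a
*synthetic stand-in* with the structural anchors of the German value set:
$u(11111) = 1$ exactly (the unique maximum) and $u(55555) = -0.661$ (the
documented floor). A real value set can be supplied as a drop-in CSV with
columns `dimension`, `level`, `decrement`.

**QALYs.** Utilities at the four assessments are assumed to follow a
linear trend between consecutive time points. With reference days
$(d_{01}, d_{12}, d_{23}) = (30, 150, 180)$,

$$\mathrm{QALY} = \sum_{k} d_k \frac{u_{k} + u_{k+1}}{2} \Big/ D,$$

where $D$ is the annual denominator. The published formula figure for this
trapezoid is not machine-readable in our source, so the formula above is a
reconstruction of the stated "linear trend" assumption, which is also
standard practice in trial-based evaluations. Whether the original
denominator was 360, 365 or 365.25 days cannot be adjudicated from the
published point estimates; we default to $D = 365$ and expose it as
`qaly_denominator` in `derive_outcomes()`. Follow-up covers 360 days, so
the attainable range is $(360/365)\,[-0.661, 1]$.

**PHQ-9 and depression-free days.** The PHQ-9 total is the sum of nine
items scored 0–3; severity bands are 0–4 none/minimal, 5–9 mild, 10–14
moderate, 15–19 moderately severe, 20–27 severe. A day is fully
depression-free below a PHQ-9 of 5, not at all at 15 or above, with linear
interpolation between: $p(x) = \min(1, \max(0, (15 - x)/10))$. Because
$p(5) = 1$ under the interpolation formula, the open/closed boundary at 5
is immaterial; we implement $x \le 5 \Rightarrow 1$. DFDs integrate
$p(\cdot)$ over the linearly interpolated PHQ-9 trajectory. The
composition is piecewise linear, so the integral has a closed form per
segment (`dfd_auc()`); the test suite checks it against 10,000-step
trapezoid quadrature to $10^{-6}$ days. DFDs are reported in days so they
match Euro-per-DFD willingness-to-pay thresholds.

## Costing

Resource-use counts per follow-up window (GP visits, specialist visits,
psychotherapy sessions, psychiatric contacts, non-physician services,
in-patient days, medication items, formal nursing care hours) are
multiplied by unit costs and inflated to 2022 Euros with a consumer price
index: `adjusted = amount * cpi[2022] / cpi[price_year]`. The shipped
unit-cost table, CPI series and labour-cost parameters are synthetic
stand-ins for the German standard unit-cost compendium, pharmacy retail
prices and labour-cost statistics, which are proprietary or unwieldy;
real tables drop in as CSVs. Productivity losses from sick-leave days use
the human capital approach (gross labour cost per day); informal care
uses the replacement cost approach (social-work sector wage plus non-wage
labour costs per hour). Perspectives: societal = direct + informal care +
indirect; payer = direct costs only. Intervention costs are never added
(they were negligible by design in the trial). Baseline resource use
enters the models only as covariates and is never costed into follow-up
totals.

## The synthetic trial generator

The generator is first-class, tested code; its defaults are the study
conditions.

* **Design.** 329 participants per arm (987 total), 64 practices nested in
  5 centres, 1:1:1 individual randomisation. Practice and centre random
  intercepts (sd 0.02 and 0.01 on the utility scale) create the clustering
  the mixed models assume.
* **Latent health.** A shared latent factor couples the EQ-5D index and
  the PHQ-9. Baseline PHQ-9 totals are drawn from a latent severity
  distribution truncated at the inclusion threshold of 10 and calibrated
  so the included sample has mean ≈ 13.5, sd ≈ 3.3; the baseline index is
  calibrated to mean ≈ 0.675, sd ≈ 0.261. Health improves over follow-up
  in all arms (index ≈ +0.14, PHQ-9 ≈ −4 by 12 months). Arm effects are
  additive utility shifts applying from the first follow-up on (with a
  documented closed-form latent QALY difference,
  `generator_expected_qaly_diff()`) and multiplicative cost-intensity
  shifts; both default to null. A utility shift propagates to the PHQ-9
  scale at −20 points per utility unit, so effect heterogeneity is visible
  in both effect measures.
* **Observed instruments.** Five-digit states are obtained by giving each
  dimension a noisy share of the total latent decrement and snapping to
  the nearest level decrement, so downstream code consumes genuine
  states, at the price of a small attenuation of latent arm shifts
  (covered by a generator test). PHQ-9 item vectors are sampled uniformly
  among the 9-tuples of 0–3 consistent with the target total, so
  item-level inputs exist for DFD scoring.
* **Costs.** Per category and window, counts follow a two-part process:
  zero with the configured probability, otherwise a positive count driven
  by a gamma-distributed participant intensity (right-skewed, zero
  inflated), linked to worse baseline health. Recall windows are set to
  the inter-assessment intervals (30/150/180 days) so follow-up costs tile
  the year without overlap; the original recall wording is not public, so
  this tiling is an explicit assumption.
* **Missingness.** Whole follow-up assessments are set missing via a
  logistic model on fully observed baseline predictors (non-native
  speaker, smoker, baseline EQ-5D index and PHQ-9, GP visits, addiction) —
  missing at random by construction. The intercept is calibrated by
  bisection so the expected overall missing fraction hits the 20% target;
  independent 20% per time point leaves ≈ 51% of participants complete,
  matching the complete-case fraction reported for the original trial.
  The MINI diagnosis flag at 1 month is missing by the same model.

What the generator does *not* emulate: recruitment flow and exclusion
pathways, item-level EQ-5D response styles, non-linear or episodic
depression trajectories, informative (not-at-random) missingness, and any
true effect of feedback. Passing tests therefore demonstrate that the
pipeline recovers known truths under the trial's design assumptions — not
that those assumptions hold in the real data.

## Multiple imputation

No chained-equations imputation package is part of this stack, so the
imputer is implemented here. Missing values are imputed at the score level
(EQ-5D index, PHQ-9 total, per-window resource counts, sick days,
informal-care hours, MINI flag), not at the item level and not at the
derived QALY/cost level: the assessment data are imputed and outcomes
derived afterwards, which keeps type invariants checkable. Conditional
models are predictive-mean matching (PMM) with Bayesian parameter draws
(normal posterior draw of the coefficients, scaled-inverse-chi-squared
draw of the residual variance) and k = 5 nearest donors, with the donor
search in compiled code; the binary MINI flag uses posterior logistic
draws. Because PMM imputes observed donor values, imputed EQ-5D indices,
PHQ-9 totals and counts automatically satisfy their range and typing
invariants. The predictor matrix contains all baseline covariates, arm,
baseline scores, *centre* dummies and the same variable at the other
follow-up time points; practice dummies (64 levels) were rejected as
rank-unstable at subgroup sizes. Variables are visited in ascending order
of missing fraction; M = 20 datasets, 10 sweeps by default, with a chain
mean/variance trace retained for convergence checks. Observed cells are
never altered; the stack is fully determined by (data, M, iterations,
seed).

## Estimation

* **Effects (QALYs, DFDs, net benefit):** linear mixed models (REML) with
  random intercepts for practices nested in centres; fixed effects are the
  two intervention contrasts against no feedback plus the adjustment set:
  age, gender (female reference; diverse retained unless empty), education,
  city size, living situation, baseline EQ-5D and PHQ-9, depression
  history, pregnancy, breastfeeding, and baseline in-patient days, GP
  visits, medication count and sick days.
* **Cost aggregates:** gamma log-link mixed models with the same fixed and
  random structure. Zero totals are shifted to EUR 0.50 (half the smallest
  plausible unit; gamma support excludes zero) with the affected count
  recorded — the original handling of zeros is undocumented, so this is a
  declared choice, not an inference.
* **Single categories / indirect costs:** a two-part model — logistic
  occurrence, gamma log-link intensity on the positives — with the
  marginal arm effect combining both parts on the log scale,
  `log(p_arm/p_ref) + beta_intensity`, occurrence probabilities evaluated
  at the reference arm's mean linear predictor, and a delta-method
  standard error.
* **Fallback:** when a mixed-model optimiser fails or returns a
  non-positive-definite Hessian, the documented fallback is the fixed
  model with practice-clustered sandwich covariance, tagged in the
  result's `method` field so pooled outputs disclose it.
* **Inference:** Wald tests with a residual degrees-of-freedom
  approximation (n − p, declared in the fit metadata), 5% two-sided
  significance, no multiplicity adjustment. Rubin pooling uses
  $T = \bar W + (1 + 1/M)B$ with Barnard–Rubin adjusted degrees of
  freedom.
* **Baseline balance:** each baseline variable regressed on the arm
  indicators — OLS (continuous), binary logistic (binary), multinomial
  logistic (multi-category, joint Wald test per contrast) — reported
  against the no-feedback reference.

## Decision analytics

Unadjusted ICERs divide the difference in raw arm means of
across-imputation-averaged per-participant costs by the corresponding
effect difference, with dominance classified on the incremental plane and
the ratio undefined at zero effect difference (cost-minimisation). CEACs
come from net-benefit regressions: for each willingness-to-pay value
$\lambda$ in EUR 0–160,000/QALY (step 10,000) or EUR 0–200/DFD (step 20),
the per-participant net monetary benefit $\lambda \cdot E_i - C_i$ is the
outcome of the same linear mixed model, fitted per imputed dataset and
Rubin-pooled *before* converting to a probability — pooling probabilities
instead of coefficients was considered and rejected, since the trial's
analysis pools model results. The cost-effectiveness probability uses the
half-p rule: $1 - p/2$ if the pooled coefficient is positive, $p/2$ if
negative, 0.5 at zero (a t reference; the normal-vs-t choice only enters
through the pooled p-value). All comparisons are pairwise against no
feedback; no three-arm contrast is emitted.

Scenarios: *payer* uses payer-perspective totals and drops baseline sick
days from the covariates; *complete case* re-runs the single-dataset
analysis on participants with fully observed 12-month societal costs and
QALY inputs (no re-imputation); *dfd* swaps the effect measure and grid.
Subpopulation analyses split every imputed dataset by gender, depression
history, addiction, or the (imputation-specific) MINI-confirmed diagnosis
at 1 month, then rerun the pipeline per level with a reduced covariate
set — pregnancy, breastfeeding and living situation dropped, city size
binarised — because strata leave too few observations per level. The
Euro-per-DFD decision threshold is accepted as a configuration scalar and
never derived (its published derivation via household-income weighting is
out of scope).

## Numerical and reproducibility choices

* One master seed; generation, missingness and imputation draw from
  deterministic substreams, so `run_all()` reproduces byte-identical CSV
  outputs and manifest digests.
* PMM ties are broken by a seeded uniform draw among the k nearest
  donors (in the compiled matcher, via R's RNG).
* Degenerate inputs: empty factor levels are pruned from model matrices;
  a subgroup level with fewer than 10 members is skipped with a warning;
  a cost category with all-zero occurrence in an arm flags separation;
  non-converged fits are excluded from pooling with a warning rather than
  silently averaged.
* Problem sizes in the validation suite were chosen to make Monte-Carlo
  error small relative to the checked tolerances while keeping a default
  run on one CPU practical: 200 replicates for the coverage and
  imputation-bias studies (n = 900 outcome-level; n = 225 with M = 20 for
  the imputation study), 500 permutation replicates for size calibration,
  1000 random trajectories for the DFD quadrature oracle, and a 50-per-arm
  smoke run for end-to-end byte-identity.

## Known limitations

The generator's calibration matches first and second moments of the
published baseline characteristics, not full distributions. The EQ-5D
discretisation attenuates latent utility shifts by roughly 20–30%, so
generator-level effect injection is suitable for power-style and
heterogeneity checks but estimator validation simulates at the outcome
level. The imputer assumes MAR given baseline covariates (as did the
trial); not-at-random sensitivity analyses are out of scope. The residual
degrees-of-freedom approximation is anti-conservative relative to
Satterthwaite/Kenward-Roger in very small subgroups; with fewer than ~30
fixed-effect parameters and n ≥ 150 per analysis the difference is
negligible at the reported precision.
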