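---
title: "Phenotyping weight-loss response to GLP-1 receptor agonists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping weight-loss response to GLP-1 receptor agonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Weight-loss outcomes under glucagon-like peptide-1 receptor agonists
(GLP-1RAs: semaglutide, tirzepatide and earlier agents) are strikingly
heterogeneous in routine care: the same drug can produce anything from
sustained double-digit percent weight loss to no change or early loss
followed by regain. `glp1traj` implements, end to end, the analysis style
used for large retrospective EHR cohorts of GLP-1RA users: an eligibility
funnel over longitudinal prescription and weight tables, a four-way
trajectory phenotype, population-level trajectory curves reaching decades
before treatment, brand-stratified contingency statistics, age/sex
propensity matching, and a phenome-wide pre-treatment disease screen.

Because the EHR data such studies run on are protected and cannot be
redistributed, the package ships a synthetic-cohort generator with known
ground truth (latent response classes, planted disease enrichments,
class-conditional demographics). Every downstream stage is exercised and
tested against that ground truth; nothing in the pipeline can read the
latent labels, which live in a separate truth sidecar.

## Cohort definition

Patients qualify with at least 3 GLP-1RA orders whose first and last order
span at least 30 days ("at least one month" is operationalised as 30
calendar days, consistent with the 30-day windowing used throughout), no
pre-index history of bariatric surgery, a baseline weight, and at least one
weight strictly inside the first post-treatment year.

* The **index date** is the date of the first GLP-1RA prescription.
* The **baseline weight** is the measurement closest to the index date in
  the closed window `[index - 90 d, index]`; an index-day weight is
  eligible, and same-day duplicates are averaged before the closest-date
  rule is applied.
* The post-treatment observation window is `(index, index + 365 d]`;
  requiring a weight *strictly after* the index day resolves the ambiguity
  of an index-day-only follow-up in the conservative direction.
* Bariatric surgery *after* the index date does not count as "history" and
  does not exclude.
* Weights are normalised to kilograms (lb × 0.45359237) and gated to the
  plausibility range (20, 400) kg; the number of dropped rows is logged.
* Age at index is whole calendar years elapsed since birth.

A `FunnelReport` records the patient count after each stage; counts are
non-increasing by construction and the funnel is checked for monotonicity.

## The four-way response phenotype

Percent weight change is computed against baseline for every measurement,
`100 (w - b) / b` (negative = loss). Within `(0, 365]` days the classifier
derives the maximum loss, the nadir (earliest measurement attaining the
minimum, as the tie rule), and the regain from nadir to the **last**
first-year observation, measured in percentage points of baseline. The
categories are:

| category | rule |
|---|---|
| regainer | max loss ≥ 5% **and** regain ≥ 5 points (checked first) |
| super | max loss ≥ 15% |
| moderate | 5% ≤ max loss < 15% |
| minimal | max loss < 5% |

Two genuinely open conventions are fixed here and exposed as configuration:

* **Super boundary.** Definitions of "more than 15%" and "at least 15%"
  both circulate; we use `>= 15` as the default because the detailed
  methods convention wins over abstract shorthand, and expose
  `super_comparator = ">"` for the alternative.
* **Regain reference.** Regain is assessed at the last first-year
  observation by default (`regain_mode = "last"`); the stricter "any
  post-nadir measurement regaining ≥ 5 points" is available as
  `regain_mode = "any"`.

Regain takes precedence over the loss-depth categories. This is forced by
the arithmetic of the published cohorts: the four category counts sum
exactly to the analytic cohort size, so the categories must partition the
cohort, and a patient losing 16% then regaining 6 points must land in
exactly one bin (regainer).

## Population trajectory curves

Measurements are aggregated into 30-day windows, half-open
`[t - 15, t + 15)` so that a measurement never contributes to two windows
of the default grid (0, 30, …, 360 days post; −7300 … 0 pre). Each patient
contributes the mean of their own measurements in a window; the curve value
is the mean of patient-level means and uncertainty is `SEM = sd / sqrt(n)`
over patient means (sample sd, `n - 1`). A single-patient window reports
`SEM = 0` with a flag. Historical (pre-index) windows with fewer than a
configurable floor of patients (default 20) are suppressed — the grid
spacing and floor for the multi-decade curve are not pinned down by any
published convention, so both are arguments.

Curves are smoothed with a Savitzky–Golay filter (window 5, polynomial
order 3), which reproduces any cubic exactly — the central convolution
weights are `(-3, 12, 17, 12, -3)/35` — and fits the nearest five points at
the edges. Suppressed interior windows are linearly interpolated before
filtering and re-masked afterwards so the filter always sees an equally
spaced series; series shorter than the window pass through unchanged with a
warning.

`restoration_lookback()` compares the post-treatment mean weight (absolute
kg) with the historical curve and returns the earliest pre-index time whose
window mean is within a tolerance (default 1 kg), i.e. "treatment restored
the weight of N years ago".

## Brand-stratified statistics

Patients whose entire GLP-1RA history carries one brand form that brand's
exclusive cohort (Bydureon and Bydureon BCise are merged as
pharmacologically equivalent); switchers are excluded from brand analyses.
Per brand × category the package reports counts, percentages and **Wilson
score** intervals — preferred to Wald intervals near the boundaries — and
between brands it reports odds ratios with the log-scale **Wald** interval
and test, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Odds ratios compare
outcome-vs-rest within two brand-exclusive cohorts; this convention
reproduces the published ratios from the published counts (see the
acceptance script). Zero cells receive the Haldane–Anscombe 0.5 correction
with a flag; the published tables never need it, but synthetic small strata
can.

Categorical baseline comparisons use the uncorrected Pearson chi-square
(Yates correction is available as a flag but off by default, matching
large-sample EHR practice); all-zero rows/columns are dropped with a
warning and degenerate remainders return `NA` rather than a spurious
p-value.

## Propensity matching

The propensity model is a maximum-likelihood logistic regression of
super-responder membership on age and gender (male = 1, female = 0),
optimised by L-BFGS with a 1000-iteration cap and a 1e-6 gradient-norm
tolerance. Covariates enter raw: with two well-scaled covariates a
quasi-Newton optimiser needs no standardisation and the coefficients stay
interpretable. Rows missing either covariate are excluded before fitting.
Complete separation produces a warning and capped coefficients, never an
error. The fit is cross-checked against `stats::glm` in the test suite.

Greedy 1:1 nearest-neighbour matching without replacement uses a caliper of
0.1 on the raw probability scale (not the logit — the caliper is defined on
"propensity scores"). Two details are under-determined by any published
description and are fixed for reproducibility, with the consequences
documented in tests: treated patients are processed in descending score
order (ties by id), and equidistant controls resolve to the lower id.
Matching is deterministic given the input ids — no randomness is involved.
Balance is reported as standardised mean differences,
`(m_t - m_c) / sqrt((v_t + v_c)/2)`, with constant covariates flagged at
SMD 0.

## Phenome-wide pre-treatment screen

Phenotype mentions carry qualifier triplets (subject, temporality,
certainty). The screen keeps confirmed + current + patient-attributed
mentions; **structured** diagnosis codes pass by definition, since the
qualifier machinery exists to contextualise free-text mentions and coded
diagnoses carry no such context. Prevalence counts each patient once per
concept within the closed window `[index - 365 d, index - 30 d]` — the
30-day blackout avoids diagnoses triggered by the initiation visit itself,
and the boundary convention (both ends inclusive) is ours to fix.

Per concept the screen reports the rate ratio (prevalence in super
responders over prevalence in the comparator), an uncorrected chi-square
p-value (expected cells < 5 flagged), and a Benjamini–Hochberg adjusted
p-value. The BH family is all concepts within one drug × cohort-pair
comparison by default — matching per-drug reporting — with a pooled global
family available (`fdr_family = "global"`). A zero comparator count leaves
the RR undefined and excluded from ranking but still reported.

Heatmap rows are diseases that are significant (FDR p < .05) **and** strong
(RR > 2 or RR < 0.5) in at least one drug; per drug up to five highest-RR
and five lowest-RR candidates are kept, ties broken by smaller FDR p then
lexicographic concept id (a deterministic rule where none is prescribed).

## The synthetic cohort generator

The generator emulates the study conditions the pipeline is meant for:

* **Brand mix and class mixes.** Defaults follow the published
  brand-exclusive cohorts: super-responder rates of 34% (Zepbound), 26%
  (Wegovy), 24% (Mounjaro) and 10% (Ozempic), moderate response at 40–42%
  everywhere, with the remainder split between minimal and regain so each
  brand's four proportions form a simplex.
* **Post-treatment curve family.** Saturating-exponential loss
  `b (1 - A/100 (1 - e^{-t/tau}))`, with a piecewise-linear rebound after a
  nadir time for regainers. Only empirical curves are published; this
  family reproduces the three qualitative shapes (continued loss, shallow
  plateau, reversal) with 2–3 parameters per class. Defaults: super
  `A = 19, tau = 120 d` (≈ 18% mean loss at one year), moderate
  `A = 10.3, tau = 90 d` (≈ 10%), minimal `A = 1.2, tau = 100 d`
  (negligible change), regainer `A = 10, tau = 60 d`, nadir day 150,
  rebound 0.045 %/day (≈ 8–9 points regained by year end). The minimal
  amplitude and the rebound slope are set so the planted classes sit well
  clear of the 5-point classification boundaries relative to measurement
  noise — the generator's contract is that the classifier can recover the
  configured class mix to within binomial error, which the acceptance
  suite verifies.
* **Pre-treatment drift.** Linear per-class drift as percent of baseline
  per year over up to 20 years. No per-class drift rates are published;
  the defaults are back-solved from the restoration claims — a super
  responder losing ≈ 18% in year one returns to the weight of ≈ 20 years
  earlier iff drift ≈ 0.9%/yr, and the moderate 10%-loss / 10-year analogue
  gives 1.0%/yr — and remain configurable. The minimal class drifts 0.05%/yr
  (nearly flat), matching its described pre-treatment trajectory.
* **Visit process.** Post-treatment visits are homogeneous Poisson (3 per
  month, the middle of the reported 2–4 clinical documents per patient per
  month), with weights recorded at 35% of visits; historical weights arrive
  at 2 per year — older EHR data are sparse. 93% of patients have a weight
  in the 30 days before the first prescription (initiation usually triggers
  a weigh-in); the remainder exercise the baseline-availability funnel
  stage.
* **Measurement noise** is i.i.d. Gaussian with sd 0.8 kg — short-term
  scale, clothing and rounding variability after unit harmonisation.
* **Demographics** are class-conditional distribution maps, not a causal
  model: super responders mean age 51 vs 55 elsewhere, 80% female vs
  58–65%, and a white-enriched race mix — exactly the imbalance the
  propensity-matching stage exists to remove, which is all the emulation
  that stage needs.
* **Diseases** are Bernoulli per patient with class-conditional prevalence
  `p exp(log RR)` capped at 1, emitted as pre-index mentions plus
  qualifier-noise mentions (negated / past / other-subject / suspected) on
  unaffected patients, so the qualifier filter has real work to do. The
  default panel plants enrichments at the scale of the published findings
  (psoriasis RR 2.5, fibromyalgia RR 0.2, osteoarthritis RR 0.5 among super
  responders) over a null background used for FDR calibration. About 2% of
  patients carry pregnancy diagnoses in the pre-index year and 35% carry
  ≥ 3 diabetes codes in the 5 pre-index years, feeding the baseline flags.
* **Non-compliant patients** (10%) receive fewer than 3 orders or a
  sub-30-day span so the exposure filter has genuine attrition.

What the generator does **not** emulate: dose and titration structure,
adherence decay, switching between brands (brand assignment is fixed per
patient), secular drug-availability trends, correlated measurement error,
missing-not-at-random visit patterns tied to weight change, disease-disease
comorbidity structure, and any causal pathway from diseases to response
class (enrichments are planted marginally). Passing tests therefore
demonstrate that the pipeline's arithmetic and contracts are correct under
known ground truth — not that the defaults reproduce every property of real
EHR data.

## Numerical and degenerate-input choices

* Savitzky–Golay on series shorter than the window: raw pass-through with
  warning; interior `NA`s interpolated and re-masked.
* SEM with one patient: 0 with a flag (undefined variance convention).
* Same-day duplicate weights: averaged, then the closest-date rule.
* Odds-ratio zero cells: Haldane–Anscombe 0.5 with `continuity_applied`.
* Chi-square degenerate tables: `NA` with a warning, never an error.
* Zero comparator prevalence: RR undefined, flagged, excluded from ranking.
* Propensity separation: warning, capped coefficients, scores still
  emitted.
* All stages are deterministic given the configuration seed; the pipeline
  fans a single seed out to per-stage streams by fixed offsets, and reruns
  are byte-identical.

## Problem sizes

The test suite runs generator cohorts of 120–3,500 patients (up to 20-year
histories where the historical curve is under test, 1–5 years elsewhere),
20 seeds for the screen calibration/power checks and 10 for the matching
balance checks; the acceptance script runs the full pipeline at 5,000
patients. These sizes keep every Monte-Carlo bound comfortably resolvable
while the whole suite stays in the tens of seconds to a few minutes.

## Known limitations

* The generator's visit process is independent of weight trajectory;
  informative observation (sicker or heavier patients weighed more often)
  is absent, so selection effects of real cohorts are not reproduced.
* The regain phenotype depends on the last observed measurement; with
  sparse late-year sampling the observed regain underestimates the latent
  rebound near the 5-point boundary.
* Propensity matching adjusts for age and gender only, by design — it
  removes the configured demographic imbalance and nothing else; it is not
  a comprehensive confounding adjustment.
* The screen treats concepts independently; no ontology rollup or
  correlation-aware multiplicity control is attempted.
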