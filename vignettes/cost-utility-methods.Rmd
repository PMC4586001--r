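---
title: "Methods: trial-based cost-utility analysis with cueval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis with cueval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cueval)
```

`cueval` implements a complete trial-based cost-utility analysis for a
two-arm randomised comparison of patient-education strategies in cardiac
rehabilitation: a "learning and coping" (LC) arm that adds individual
clarifying interviews, weekly team evaluations and expert-patient
co-teaching to the standard 8-week group programme. This vignette is the
package's own account of the methods: the models, the parameters that
matter, the numerical conventions, and the design choices made where the
design was genuinely open.

## Micro-costing model

One course is costed bottom-up as role-hours times unit wages
(`course_cost()`). For the two staff roles (nurse, physiotherapist) the
planned contact hours — training sessions, education sessions, individual
interviews, weekly team evaluations — are multiplied by a **load factor**
(dimensionless, default 1.5, `>= 1`): staff are productive about 45
minutes per hour (breaks, walking between locations), and the remaining
loading covers vacation, sickness and continuing education. The loaded
increment is reported as its own "load for unproductive time" line.
Expert patients (lay educators, retired former patients) are priced
*unloaded* at a flat pensioner net wage (108 DKK/h in the shipped 2013
catalogue) — they have no employment overheads to load — and their
hospital-paid transport enters as a per-course amount. A hospital
**overhead rate** (fraction of staff cost, default 0.21) covers capital
and indirect costs and is applied to the sum of the role subtotals. The
per-patient intervention cost divides the course total by the number of
patients sharing a course (default 10).

Two numerical conventions matter here. First, all arithmetic is done at
full precision; only *reported* lines (overhead, totals, per-patient
costs) are rounded to whole DKK, which is what makes the shipped worked
example reproduce integer for integer (LC course 48,072; standard 27,348;
4,807 vs 2,735 per patient; increment 2,072). Second, the expert
transport line is carried as a per-course constant in the course-spec
fixture rather than derived from the per-way tariff, because the tariff
arithmetic (48 ways x 49 DKK) does not reproduce the recorded per-course
amount (2,304 DKK); the fixture preserves the recorded value.

## Per-patient costs and perspectives

`compute_patient_costs()` attaches seven category columns and a
perspective-filtered total. The **healthcare** perspective counts the
intervention's formal-care share, primary care, prescribed medicine and
secondary care; the **societal** perspective adds productivity loss,
informal time and patient transport. Design choices, made once:

* **Intervention attribution under the healthcare perspective**: staff
  costs plus overhead on staff, plus expert transport (the hospital pays
  it); expert-patient *time* is informal and counts only societally.
  A consequence is that the societal-minus-healthcare gap decomposes into
  the three societal categories *plus* this attribution difference; the
  tests assert the decomposition explicitly.
* **Productivity loss**: weeks of inability to work (sick leave,
  re-schooling, disability pension) x a 37-hour working week x the gross
  hourly wage, and zero for patients who reach the pension age of 67
  before the 5-month follow-up ends. The 37-hour week is the Danish
  standard full-time week; the motivating study prices sick weeks without
  stating weekly hours.
* **Informal time**: attended course hours (1.5 h per training or
  education session, 1 h per interview) plus travel time (2 x 20 min per
  contact), valued by the opportunity-cost method. The general rule —
  leisure time at the net wage, productive time at the gross wage — is
  keyed on pension-age status: pensioners' time is leisure (net), younger
  patients' time displaces productive time (gross).
* **Transport**: contacts x 2 ways x 10 km at the government car tariff
  (3.82 DKK/km, 2013). "Contacts" are attended training plus education
  sessions plus interviews (LC only); this definition reproduces the
  recorded mean kilometres to within a percent.
* **Salary bands**: gender x 5-year age bands, age fixed at
  randomisation; ages above the top band clamp to it. Only the four
  60-64-year-old cells of the shipped table are national figures — the
  rest is a synthetic but plausible age profile anchored on them (the
  file is named `salary-table-synthetic.csv` accordingly).
* **Price year**: all amounts are 2013 DKK; `adjust_price_year()` inflates
  by CPI ratio where inputs predate 2013. No discounting is applied over
  the 5-month horizon (a rate parameter exists and defaults to zero).

## QALYs

`qaly_auc()` integrates the piecewise-linear utility curve through the
SF-6D measurements at 0, 2 and 5 months and divides by 12 to express
months as years, so the 5-month horizon caps QALYs at 5/12 ≈ 0.417.
Utilities outside [0, 1] are **rejected, not clamped** — SF-6D utilities
under the British preference weights live in roughly [0.30, 1], so an
out-of-range value signals data corruption upstream, never a value to
repair silently. QALYs are plain unadjusted AUC (no baseline-utility
regression): the published arm values are reproduced exactly by this
arithmetic, which is the evidence that no adjustment was involved.

## Missing utilities

Utility nonresponse in the motivating trial was heavy (≈ 42-46 % per
post-baseline timepoint) and non-monotone. Costs come from full-coverage
registries and are complete by construction; only utilities are imputed.

The main analysis uses **multiple imputation by chained equations**
(`impute_chained()`). Each incomplete utility variable gets a linear
regression on the other two utilities plus the nonresponse predictors
(arm, age, gender, attendance counts, secondary-care cost, medicine cost,
productivity-loss cost — the variables the responder/non-responder
comparison flags). Draws are *posterior* draws: the residual variance is
drawn from its scaled inverse-chi-square posterior and the coefficients
from their conditional normal, so between-imputation variance reflects
estimation uncertainty rather than just residual noise. The chain runs a
fixed 10 cycles, which comfortably exceeds the mixing needed for three
variables, and imputed values are clipped to the observed range of the
variable. Defaults: m = 20 completions — the motivating study does not
report m, and with ~40 % nonresponse a small m makes pooled estimates
noticeably unstable. Sensitivity modes: **LOCF** (baseline carried to 2
months, 2 months to 5; patients with no baseline are excluded with a
warning count) and **complete case** (patients with all three utilities
observed).

**Combining imputation with the bootstrap** has no single standard
recipe. `cueval` imputes once to produce the m completed
datasets, bootstraps *within* each completed dataset, and pools the
draws across imputations (the point estimate is the average of the
per-imputation estimates). Pooling draws keeps between-imputation
variance in the CEAC, and makes the pooled curve exactly the
imputation-average of per-imputation curves — a property the tests
assert. The alternative (bootstrap first, impute inside each replicate)
is statistically defensible but two orders of magnitude more expensive;
it was not implemented.

## Bootstrap, net benefit, CEAC

`bootstrap_incrementals()` resamples patients with replacement
**independently within each arm** (the arms are independent randomised
groups), preserving arm sizes, and records the pair of between-arm mean
differences per replicate. 10,000 replications is the default, motivated
by the strong right skew of cost data. Point estimates always come from
the original, un-resampled data.

Net monetary benefit converts a draw to money at a willingness-to-pay
threshold: NB(λ) = λ x ΔQALY − ΔCost. The CEAC reports the fraction of
draws with **strictly positive** net benefit over a grid of λ from 0 to
500,000 DKK/QALY in 1,000-DKK steps (501 points; the range follows the
motivating study, the step is ours). Ties at exactly zero count as
*not* cost-effective — conservative, and of measure zero for continuous
data. At λ = 0 the curve equals the probability of cost saving; as λ → ∞
it tends to the probability of any QALY gain (the tests pin both limits
exactly).

Confidence intervals default to the **percentile bootstrap** (2.5th and
97.5th percentiles of the draws): the published intervals are
asymmetric-capable, and percentile is the standard companion to a
non-parametric bootstrap. Normal-approximation and BCa intervals are
options; BCa needs the jackknife acceleration and is therefore only
available for single-dataset draws, not pooled MI draws.

## Sensitivity scenarios

`scenario()` expresses each sensitivity analysis declaratively:
perspective, catalogue overrides, category exclusions, imputation mode.
The five shipped scenario fixtures are: healthcare perspective; lower
therapist salaries (nurse 150, physiotherapist 120 DKK/h); no load
factor; 12 patients per course; excluding patient time. Two choices the
scenario semantics had to fix: the lower-salary scenario also rescales
the load-hour valuation (the load line is priced at the overridden wage —
mechanically unavoidable in a bottom-up costing, and in our view
correct); and the 12-patients scenario changes *only* the per-patient
divisor, leaving course content fixed. Post-follow-up hospital
admissions can be excluded via a per-patient flag carried in the data
(registry discharge dates themselves are out of scope).

## The synthetic trial generator

`generate_trial()` draws complete patient records with the structure the
pipeline consumes, calibrated to the motivating trial's arm-level
moments: 413/412 patients, age ≈ N(63, 10) discretised and clamped to
the observed ranges, 76 % male, 79/78 % ischemic heart disease,
attendance counts clamped to their ranges, utilities at the three
timepoints from an equicorrelated Gaussian copula (correlation 0.6 — a
typical test-retest value, free parameter) clipped to [0, 1], and
right-skewed registry costs from gamma distributions matched to the
published mean and SD of each category (SD = published SE x √n at the
published arm sizes; SDs are population properties and do not change
when a smaller trial is generated). Skewness via the gamma family is a
choice: skewness of trial cost data motivates the bootstrap without
pinning down a distribution family. The secondary-care categories share a latent
factor with the utility level (correlation −0.3 by default), so sicker
patients cost more; weeks of inability to work are drawn only for
patients below pension age, scaled so the population mean hits its
target.

`apply_missingness()` masks utilities either MCAR or MAR. The MAR
mechanism is a per-patient logistic propensity increasing in log
secondary-care cost and decreasing in attendance, with the intercept
calibrated by root-finding to the marginal cell rate (default 0.43,
matching one minus the average published response fractions); all three
cells share the patient's propensity. With the negative cost-utility
correlation this reproduces the qualitative finding that responders are
better off than non-responders — and it is exactly the mechanism the
chained-equation predictors can correct.

What the generator does **not** emulate: registry event histories
(admission dates, DRG codes — only their cost consequences and a
post-follow-up flag), within-patient correlation between attendance and
utilities, attendance variance beyond the clamped-normal approximation
(the published tables give means and ranges, not SDs), and any
non-random (MNAR) nonresponse. Passing tests on synthetic data therefore
demonstrate the *statistical machinery* — unbiased imputation under
MCAR/MAR-given-predictors, correct bootstrap coverage, CEAC limits —
not the clinical findings themselves, which depend on registry data that
cannot be redistributed.

Analytic expectations (`true_increments()`) account for the
discretisation, clamping and clipping: the [0,1]-clipping of utilities,
for instance, moves arm means by at most 0.002 at the calibrated SDs,
and the expected increments under the defaults are ΔCost ≈ 6,013 DKK and
ΔQALY ≈ 0.0054 — the calibration targets.

## Numerical and testing conventions

* Whole-DKK rounding only at reported lines; QALYs at full precision,
  rounded to 3 decimals only for display.
* All randomness flows through explicit seeds; child seeds for pipeline
  stages are derived deterministically from one master seed, so a run is
  reproducible from its provenance record (seed + config hash).
* Degenerate inputs are defined: zero-variance generators produce
  identical patients; an empty arm, an all-missing variable, a rate of 1,
  an unknown perspective or override key each raise a structured
  validation error naming the field.
* Test problem sizes are chosen to make Monte-Carlo tolerances sharp but
  cheap: exhaustive resample enumeration at n = 3/arm (the 3^3 x 3^3
  oracle), closed-form SE comparison at n = 400/arm with B = 10,000,
  moment recovery at n = 10,000/arm, imputation-bias replication at 200
  trials of n = 60/arm, end-to-end recovery at n = 400/arm, and null
  calibration over 60 replicate trials. On the imputation-bias check,
  "bias below half a Monte-Carlo SE" is read against the per-replicate
  Monte-Carlo SD of the pooled-minus-complete difference: an exactly
  unbiased imputer fails a ±0.5-standard-error-of-the-mean band about
  62 % of the time by construction, so that cannot be the intended
  operating characteristic.

## Known limitations

* SF-6D scoring from item responses is out of scope; utilities arrive as
  numbers in [0, 1].
* No MNAR sensitivity models (pattern mixture, delta adjustment).
* No probabilistic sensitivity analysis over unit costs, no EVPI, no
  parametric (normal-theory) CEACs, no ICER league tables.
* Secondary-care costs enter pre-tariffed; no DRG grouping logic.
* The salary table outside the anchored 60-64 bands is synthetic; level
  (not incremental) cost estimates inherit that approximation.
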