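---
title: "Calendar-year bias correction of eMR creatinine and eGFR decline estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calendar-year bias correction of eMR creatinine and eGFR decline estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrtraj)
library(dplyr)
```

# The problem

Serum creatinine extracted from general-practitioner electronic medical
records (eMR) extends kidney-function follow-up from a handful of years to
decades, but values measured before creatinine assays were standardized
(roughly before 2009, with heterogeneous uptake for some years after) are
systematically high relative to modern, centrally measured gold-standard
values. Because estimated GFR is a decreasing function of creatinine, the
old values depress early eGFR, and a trajectory whose early points are
biased low appears to decline far more slowly than it does. `egfrtraj`
implements a calendar-year calibration of eMR creatinine against
gold-standard study-center (SC) measurements, and the downstream trajectory
and decline machinery.

# The error model and its estimator

On the log scale we assume normality for both sources,
$X = \ln(\mathrm{crea}_{SC}) \sim N(\mu, \sigma^2)$ and
$X^* = \ln(\mathrm{crea}_{eMR}) \sim N(\mu^*, \sigma^{*2})$, with an
additive decomposition of the eMR error into a systematic component $s$ and
a mean-zero random component:

$$X^* = X + s + E^*_r, \qquad E^*_r \sim N(0, \sigma^{*2}).$$

Taking expectations gives $s = \hat\mu^* - \hat\mu$, estimated per calendar
year on the *paired* sample: persons with an SC measurement and an eMR
measurement from the same calendar year, using the eMR value closest in
time to the SC blood draw (ties broken towards the earlier date; at most
one pair per SC visit). On the original scale the bias is multiplicative —
the ratio of geometric means — and the correction factor applied to eMR
values is its reciprocal:

$$\mathrm{factor}_{year} = \frac{GM(\mathrm{crea}_{SC})}{GM(\mathrm{crea}_{eMR})}
  = \exp(-s^{year}), \qquad
  \mathrm{crea}^{corr}_{eMR} = \mathrm{crea}_{eMR} \times \mathrm{factor}_{year}.$$

Subtracting $s^{year}$ on the log scale leaves
$X^{*}_{corr} = X + E^*_r$: unbiased on average, with a purely random
residual error. The correction is valid *on average* only — it cannot
recover person-specific truth, because the assay behind any individual
measurement is unknown.

Two estimator details are configurable:

* **Minimum pairs per year** (default 100): years with fewer pairs are not
  estimated directly but filled by the proxy rules below. The default
  balances estimator noise (SE of the log factor is roughly
  $\sqrt{2}\,\sigma^*/\sqrt{n}$) against coverage of the calendar span.
* **Winsorization** (off by default): as a robustness check, each of
  $\ln(SC)$ and $\ln(eMR)$ can be clamped to its own within-year
  mean ± 3 SD before estimation, which bounds the influence of entry errors
  that survive QC.

## Proxy factors for uncovered years

Years in the data span without a direct estimate get factors by rule, each
tagged with a provenance so downstream users can see which years are
calibrated versus extrapolated:

* *Interior gaps* (`interpolated`): linear interpolation of the log bias
  between the flanking estimated years; a single-year gap is the
  exponential of the mean of the two adjacent log biases.
* *Before the first estimated year* (`boundary_carry`): the first year's
  factor is carried back. This is the strongest assumption in the package —
  it extends a factor estimated in one year across potentially decades of
  older assays.
* *After the last estimated year*: factor 1.0 (`unity`, no correction) when
  the last estimate is already within `unity_threshold` (default 0.05) of
  one — the situation after assay standardization — otherwise the last
  factor is carried forward. The threshold generalizes the hard-coded
  "no correction after the last calibrated year" behaviour to datasets
  whose last estimate is not yet near unity.

# Quality control

Raw eMR creatinine passes a fixed sequence, each record receiving exactly
one terminal status (the counts partition the input): technical errors
(non-numeric, non-positive, missing date — a pluggable predicate), values
above the plausibility maximum (default 6524 µmol/L, the highest credible
recorded value), values below the limit of detection, duplicates (same
person, date, and value; the first occurrence in input order is kept —
same-day *differing* values are retained as plausibly distinct draws), and
values below the limit of quantification, which are floored to the LoQ
rather than dropped. The default LOD/LoQ of 18 µmol/L is a placeholder:
these are properties of the originating laboratories, which eMR extracts do
not record, and should be set per dataset. SC records bypass QC: they are
measured by one assay in one laboratory under a standardized protocol.

# eGFR, trajectories, censoring

eGFR uses the race-free CKD-EPI 2021 creatinine equation (κ = 0.7/0.9,
α = −0.241/−0.302 for women/men, unit conversion 88.42 µmol/L per mg/dL).
Age at exam is computed from year and month of birth with the day imputed
as the 15th. eGFR is not capped; extreme values are a display concern, not
a data one.

SC- and eMR-derived assessments are merged by person and date; same-date
assessments from the two sources are both kept. For decline estimation a
trajectory is censored after the earliest of the first severe kidney event
(AKI, ESKD, dialysis, transplant, nephrectomy — diabetes annotates but
never censors) and the first assessment with eGFR < 15; that triggering
assessment is retained, since it defines onset, and "after" is exclusive of
the event date. Assessments within ±183 days of a pregnancy are removed
(the six-month window is fixed in days for reproducibility).

Annual decline is the two-point annualized difference
$(\mathrm{eGFR}_{first} - \mathrm{eGFR}_{last}) / \mathrm{years}$, positive
when kidney function falls — the sign convention under which age, smoking
and diabetes effects are positive. Eligibility requires two censored
assessments at least 365 days apart. The cohort summary is the arithmetic
mean with a normal-approximation interval (± 1.96 · SD/√n); the risk-factor
models are unweighted OLS over persons (one "genetic" model: age − 40, sex,
variant allele dosage; one "lifestyle" model: age − 40, sex, ever-smoking,
obesity = BMI ≥ 30, diabetes), with listwise deletion and loud failure on
zero-variance or collinear designs. The peri-AKI analysis selects, for each
person with incident AKI (first AKI record on or after their first
assessment), the assessment at least 183 days before the event closest to
that mark and likewise after, and annualizes the difference.

# The synthetic cohort generator

The generator exists so that every stage can be validated against known
truth. Its defaults describe one fixed set of study conditions:

* **Cohort**: entry ages uniform 40–69 at an SC baseline visit in
  2007–2010; 40% with an SC follow-up in 2012–2013; sex-specific lognormal
  baseline creatinine (medians ≈ 62/78 µmol/L, log-SD 0.15) inverted
  through CKD-EPI 2021 to a baseline eGFR intercept.
* **Trajectories**: latent eGFR linear in time with population mean slope
  1.0 mL/min/1.73m²/yr, person-level slope SD 0.3, and covariate effects
  (age 0.005/yr, male 0.10, smoking 0.026, obesity 0.010, diabetes 0.383,
  variant allele 0.052 per dose). Covariate contributions are centered at
  the sample mean, so the cohort mean slope equals the configured mean and
  regression recovery and mean-decline recovery can be tested against the
  same truth.
* **Measurements**: true creatinine is the closed-form piecewise inverse of
  CKD-EPI 2021 (each branch solved exactly; the branch consistent with its
  own knot condition selected). SC values observe truth with lognormal
  noise (log-SD 0.05) and no bias; eMR values are additionally *divided* by
  the year's bias factor (0.84…0.97 ramp over 2007–2013, 0.84 before, 1.0
  after), so early assays read high. eMR visits are Poisson per person-year
  with intensity increasing as latent eGFR falls (the informative-visit
  mechanism that makes high-count members sicker) and scaled by a calendar
  coverage ramp (full from ~2004, thinning exponentially backwards) that
  mirrors the growth of routine EHR volumes and concentrates visits where
  same-year pairs are possible.
* **Events**: constant per-person-year hazards; AKI (1e-3/yr) triggers an
  acute 20-unit latent drop with 70% recovery over a year. The AKI hazard
  is deliberately higher than real-world incidence so that cohorts of a few
  thousand persons contain enough qualifying peri-AKI pairs to exercise the
  window rule; the allele frequency (0.2) is a generic common-variant
  value. A small rate of corrupt rows (duplicates, above-maximum,
  below-LOD) is injected to exercise QC.

What the generator does *not* emulate: real read-code vocabularies,
assay-level (rather than calendar-level) bias structure, non-linear
trajectories other than the AKI episode, correlated missingness of
covariates, and the absolute scale of real biobank data. Passing tests
therefore demonstrate that the estimators recover the parameters of this
generating process, not that the correction factors transfer to any
particular health-care system.

# Numerical choices and degenerate inputs

Dates are ISO 8601; all year arithmetic uses the calendar year of the exam
date and 365.25 days per year. Ties in pairing go to the earlier eMR date;
duplicates keep the first record in input order; the bias table refuses to
build from zero estimated years; correction refuses records whose year the
table does not cover (naming the year); regressions refuse zero-variance
and collinear designs (naming the columns) rather than silently dropping
terms; the CKD-EPI knot is continuous by construction and the inverse is
exact to floating point.

Problem sizes in the shipped validation runs were chosen for single-CPU
reproduction: 2,000-person cohorts for end-to-end recovery (50 replicate
seeds), 5,000 pairs/year for the bias-estimator Monte Carlo (20 seeds), and
2,500-person cohorts for regression recovery (20 seeds).

# Known limitations

* The correction is unbiased on average but each year's factor is estimated
  from a finite paired sample; its sampling error shifts *all* corrected
  values of that calendar year coherently. The person-level interval around
  the mean decline does not see this shared component, so at small pair
  counts (hundreds per year) the interval undercovers the true mean even
  though the point estimate is unbiased. With tens of thousands of pairs
  per year the component is negligible. Users working at small scale should
  treat the mean-decline CI as conditional on the estimated bias table.
* Carrying the first estimated factor back across decades assumes the
  pre-standardization bias was constant, which technology history does not
  guarantee; a manufacturing-date-continuous error model would need
  calibration data that eMR extracts lack.
* The two-point decline estimator ignores intermediate assessments by
  design; it is unbiased for linear trajectories but not efficient, and no
  mixed-effects or spline modelling is provided.
* Event categorization is only as good as the supplied code list; the
  shipped list is an illustrative stub, not a clinical vocabulary.
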