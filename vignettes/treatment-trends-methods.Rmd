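---
title: "Methods: register-based trends in SLE treatment exposure"
author: "sletrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: register-based trends in SLE treatment exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sletrends)
library(data.table)
```

## What the package estimates

`sletrends` implements a register-based analysis of how glucocorticoid
(GC) and hydroxychloroquine (HCQ) treatment after a new diagnosis of
systemic lupus erythematosus (SLE) has changed across calendar time.
The analysis takes three register-shaped tables — a population table, a
care-visit table with ICD-10 codes, and a pharmacy dispensation table —
and produces:

* an incident adult SLE cohort (two SLE-coded visits, ICD-10
  M32.1/M32.8/M32.9, within one year, at least one at a specialist
  department; first SLE-coded visit inside the inclusion window
  2005-07-01 to 2021-09-01; at least 2 years of prior residency; age 18
  or older; at least 1 year of follow-up),
* per-person, per-year drug-exposure measures derived purely from
  dispensations: any-use flags, cumulative prednisolone-equivalent GC
  dose, HCQ coverage intervals and the proportion of days covered
  (PDC), and 8-way treatment-combination states (GC/HCQ/
  immunosuppressant),
* temporal-trend estimates across calendar cohorts of diagnosis
  (2005–2008, 2009–2012, 2013–2016, 2017–2021): adjusted odds ratios
  from logistic regression for yearly any-use, Wilcoxon rank-sum
  comparisons of 5-year exposure, and quantile regression of 5-year
  cumulative GC dose and HCQ PDC over the percentile grid
  τ = 0.10, 0.15, …, 0.90 with person-level bootstrap confidence
  intervals.

Because individual-level Swedish register data cannot be shared, the
package ships a synthetic-register generator with known ground truth;
all statistical machinery is validated by parameter recovery on that
generator plus exact oracles on constructed inputs.

## Exposure model

**Windows.** Analysis year *k* after diagnosis is the half-open window
`[(k-1)·365.25, k·365.25)` days from the first SLE-coded visit,
truncated at the end of follow-up (`min(registration end, data end)`).
The 5-year summary window spans years 1–5. Windows, not calendar years,
are the unit of exposure assessment.

**Cumulative GC dose.** Each GC dispensation contributes
`n_ddd × ddd_mg × factor` prednisolone-equivalent mg, where `n_ddd` is
the number of WHO defined daily doses dispensed, `ddd_mg` the
substance's DDD in mg, and `factor` its potency relative to
prednisolone (prednisolone/prednisone 1, methylprednisolone 1.25,
dexamethasone 20/3, betamethasone 25/3, hydrocortisone 0.25, cortisone
0.2). The full dose of a fill is attributed to the window containing
the fill date; no smearing across windows. Only oral systemic
glucocorticoids (ATC H02AB) enter by default; infusions and in-hospital
medication are outside the dispensation register and outside scope.
The equivalence table is plain data (`gc_equivalence_table()`) and can
be replaced.

**HCQ coverage.** A dispensation of one package nominally covers 100
days; a single dispensation of *m* > 1 packages covers 75·*m* days.
Same-day fills are merged before the rule is applied. When a new fill
occurs while a supply is nominally running, the earlier supply is
treated as fully consumed at the new fill date and coverage continues
from the new fill — truncation, not stockpiling. Coverage is truncated
at the end of follow-up, and PDC is covered days divided by observed
window days. One consequence worth knowing: with multi-package
supplies the truncation rule is not monotone — an early one-package
refill after a two-package fill shortens nominal coverage from 150 to
110 days, because the earlier supply is deemed consumed at the refill.
That is the rule's intended semantics, verified against a day-by-day
consumption simulator, not an implementation artifact.

**Categories.** Average daily GC dose (cumulative dose / window days)
is binned at the guideline thresholds `{0, (0,5], (5,7.5], >7.5}`
mg/day. HCQ PDC is binned `{0, (0,0.2], (0.2,0.8], >0.8}`; the 0.8
boundary is the standard 80% adherence threshold, the 0.2 boundary
separates sporadic from partial coverage and is a package choice.

## Trend models

**Logistic any-use models.** Any-use of a drug in year 1 (or year 5) is
regressed on calendar cohort plus the adjustment covariates: age
category (18–39/40–59/≥60), sex, education (0–9y/10–12y/≥13y/missing),
birth region (Nordic/non-Nordic/missing), hospital type at diagnosis
(university/other), prior-year hospitalization days (0/1–7/>7) and
prior-year specialist outpatient visits (0–2/3–6/>6). All covariates
enter as categorical factors with explicit missing levels and the first
level as reference; odds ratios carry Wald 95% intervals and p-values.
Year-5 models are restricted to persons with at least 5 years of
follow-up *and* diagnosis in 2005–2016; the most recent cohort is
excluded from all 5-year analyses by design.

**Quantile regression.** Five-year cumulative GC dose (among persons
with ≥1 GC dispensation in those five years) and 5-year HCQ PDC (among
persons with ≥1 HCQ dispensation) are modelled by quantile regression
at every τ in 0.10–0.90 (step 0.05). The calendar-cohort coefficients
are the quantile shifts attributable to diagnosis period, read against
the reference cohort's exposure distribution. The solver
(`rq_fit()`) minimizes the check loss by an exact simplex on the
equivalent linear program: a vertex solution interpolates *p*
observations; dual multipliers are checked against `[τ−1, τ]`; a
violated row leaves the basis along its descent direction and the
entering row comes from a weighted one-dimensional search over the
piecewise-linear objective.

Two deterministic perturbations make the solver's answer unique
without affecting reported values. First, τ is shifted down by a
relative 1e-7 — far below the 1/n granularity of the dual values, far
above the 1e-9·n feasibility tolerance — so that when the minimizer is
a face (intercept-only fit with nτ an integer) the lowest vertex is
returned and an intercept-only fit equals the lower empirical quantile.
Second, ties among observations are broken lexicographically: residuals
of a fixed hash-sequence perturbation are tracked separately from the
data residuals, on their own floating-point scale, so tie-break signs
are never swamped by data round-off and the simplex cannot cycle on
heavily tied data. Coefficients are always computed from the
unperturbed data at the final basis, so interpolation and noise-free
location-shift recovery are exact.

**Bootstrap.** Confidence intervals for quantile-regression
coefficients are percentile-method intervals from a nonparametric
person-level bootstrap (default 500 replicates, 90% level, seeded);
the bootstrap standard deviation is reported as the standard error.
Replicates whose resampled design loses a factor level are dropped and
counted; more than 10% dropped is an error. No multiplicity adjustment
is made across the τ grid — each τ carries its own interval.

**Wilcoxon comparisons.** Crude cohort contrasts of 5-year exposure use
the rank-sum test with midranks; when both samples have at most 10
observations the two-sided p-value is computed by exact enumeration
over all assignments of the pooled sample (valid under ties),
otherwise by the normal approximation with tie-corrected variance and
continuity correction.

## The synthetic-register generator

The generator (`simulate_registers()`) is a design artifact: the
registers it emulates give no generative model, so the package commits
to the simplest mechanism that reproduces the published cohort
marginals, and treats those choices as fixed study conditions.

* **Demography.** Sex is Bernoulli with female probability 0.825; age
  at diagnosis is a truncated normal (mean 48.8, SD 18.1, range
  18–96); education and birth-region categories use the published
  total-column fractions. Diagnosis dates are uniform over the
  inclusion window.
* **Latent severity** is log-normal (σ = 0.5) and scales pre-diagnosis
  healthcare utilization (negative-binomial outpatient counts,
  log-normal hospitalization stays), so utilization covariates are
  informative about severity but — by construction — independent of the
  calendar-cohort treatment parameters.
* **GC exposure.** Per cohort, a use probability (0.680/0.731/0.731/
  0.683, the published year-1 proportions) and a yearly continuation
  probability (0.944/0.908/0.892/0.885, solved from the published
  year-5/year-1 ratio via p_cont = (p5/p1)^(1/4)). A user draws a
  5-year cumulative prednisolone-equivalent dose from a log-normal
  whose median is the configured per-cohort median (7500/7000/6500 mg
  published; 6000 mg chosen for 2017–2021, which a 5-year window cannot
  observe in the source data, continuing the fitted trend) with σ = 1.0
  (chosen to approximate the published interquartile range
  3000–12000 mg around 7500). The dose is spread over the active years
  with a geometric taper (ratio 0.55, reproducing the first-year-heavy
  dosing pattern) and dispensed in four fills per active year, 90% as
  prednisolone, 10% as methylprednisolone with DDD-consistent `n_ddd`.
  For a fully followed user the engine-measured 5-year dose equals the
  drawn dose exactly, so the quantile-recovery estimand equals the
  configured median difference.
* **HCQ exposure.** Initiation is Bernoulli per cohort (0.442/0.639/
  0.730/0.802, the published year-1 proportions), 0–60 days after
  diagnosis; fills of one package (10% two packages) recur every
  Uniform(80, 120) days — so realized PDC stays below 1 even for
  persistent users — until an exponential discontinuation time whose
  per-cohort hazard (0.263/0.197/0.171/0.140 per year) is solved from
  the published 5-year PDC medians (50.2/66.8/76.9%; the last cohort
  continues the trend).
* **Immunosuppressants.** Bernoulli use per cohort (0.50–0.60) with a
  class mix dominated by azathioprine, methotrexate and mycophenolate;
  quarterly fills over an exponential treatment duration.
* **Censoring.** Death and emigration act as competing exponential
  censoring hazards (0.02 and 0.005 per year); which of the two drives
  censoring in the source registers is not knowable from the published
  material, so both are exposed as configuration knobs.
* **Filter exercise.** Configurable fractions of cases violate each
  eligibility filter: prevalent cases (onset up to 4.5 years before the
  window; default 10%), recent immigrants (2%), under-18 cases (1%),
  plus 1% with onset after the window and non-case near-misses (a
  single SLE-coded visit, or a pair more than a year apart). Every
  flag is re-derived from the realized dates, so the cohort builder's
  decisions can be compared to ground truth exactly.

**Seeding.** One master seed; the population, visit and dispensation
stages seed at `seed`, `seed + 1`, `seed + 2` and draw vectorized in
fixed person order. Identical configuration and seed give bit-identical
tables (tested after serialization as well).

**What the generator does not emulate.** No treatment interruptions or
restarts (so year-5 HCQ any-use is lower than in the real registers,
whose patients stop and resume; the generator's calibration targets are
the 5-year coverage medians, not year-5 re-use), no dose titration
within a year, no biologics, no in-hospital or infusion GC, no regional
or hospital-level clustering, no calendar-time incidence drift, and no
correlation between disease severity and treatment choice within a
cohort. Passing recovery tests therefore demonstrates that the
estimators recover known trends from register-shaped data under this
mechanism — not that the mechanism is a faithful model of Swedish
clinical practice.

## Numerical and design choices

* Year length is fixed at 365.25 days; all windows are half-open;
  "within 1 year" for the qualifying visit pair means ≤ 365 days.
* Eligibility filters apply in a fixed order (window end, washout,
  residency, age, follow-up) so exclusion counts are reproducible; the
  exclusion log plus retained count always sums to the candidate count.
* Hospitalization days are clipped at the diagnosis date
  (`min(discharge, diagnosis) − admission`).
* Diagnosis date is the first SLE-coded visit ever recorded; the
  specialist requirement is evaluated over all of a person's SLE-coded
  visits.
* Percentages print half-up at one decimal (`round_half_up()`), the
  convention of the published tables; base `round()` would round half
  to even.
* The stockpiling alternative to truncation-at-next-fill is
  deliberately not implemented as a default; the truncation rule is the
  published algorithm and the package's scope.
* Missing education/birth region are explicit factor levels throughout;
  no imputation.

## Validation scale

The test suite validates the pipeline at sizes chosen for a single CPU:
coverage of the 90% bootstrap intervals is assessed over 300 outer
replicates of a two-group median-shift design at n = 2500 (true shift
−753 mg, n_boot = 200), over 200 logistic replicates at n = 5000 (true
odds ratio 0.7), and over 100 full pipeline replicates (generator →
cohort → exposure → quantile regression) at 2000 simulated persons
each, pooling the cohort-contrast coverage events per drug. The
interval-construction oracle runs 10,000 random dispensation streams;
Wilcoxon exactness is enumerated for pooled samples up to 12; the
quantile solver is checked against vertex enumeration and empirical
quantiles across the full τ grid.
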