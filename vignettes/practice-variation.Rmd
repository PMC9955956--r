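---
title: "Methods: quantifying practice variation in chronic opioid prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying practice variation in chronic opioid prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxvar)
```

## The problem

General practices differ widely in how often their patients end up on
long-term opioid therapy. Some of that variation is warranted — practices
serve different populations — but variation that persists after adjusting
for patient case mix may signal unclear clinical standards or
provider-driven prescribing. `rxvar` implements a complete pipeline for
measuring such variation from dispensing records: it classifies each
patient-year as showing chronic opioid use (prescriptions covering at
least 90 consecutive days), splits chronic use at an average daily dose of
90 mg oral morphine equivalents (OME) into chronic high-dose use, compares
each practice's observed outcome count with the count expected from its
case mix, and summarises the spread of the resulting standardized
proportions.

Because real primary-care dispensing databases are access-restricted, the
package ships a synthetic cohort generator that emulates the statistical
structure such an analysis assumes — including ground-truth labels, so
that every stage of the pipeline can be validated by recovery tests rather
than by eyeballing.

## Pipeline stages and their models

### Cohort filters

Practices qualify when their registration data meet five quality criteria
(>= 46 weeks of data, >= 85% valid ATC codes, >= 75% valid ICPC codes,
>= 500 registered patients, >= 80% full-year registration); patients
qualify when aged >= 20 on 1 January, registered the full year, and
without an active cancer diagnosis. All thresholds are inclusive — the
criteria are phrased as "at least". Patients with missing eligibility
fields are excluded and logged rather than imputed; every excluded entity
receives an exclusion-log row, so inclusion and exclusion always
partition the input.

Opioids are selected by ATC prefix `N02A`, plus `N07BC` (drugs used in
opioid dependence) under a flag whose off position reproduces the
sensitivity analysis without that group. Codeine is excluded because it is
mostly prescribed for cough; since the exclusion is a substance-level
judgement, the code list (`R05DA04`, `N02AA59`, `N02AA79`) is an argument,
not a constant, and whether combination products belong on it is left to
the caller.

### OME conversion

Each prescription is converted to total and daily OME by an exact
(ATC-prefix, route) lookup in a packaged conversion table of published
equianalgesic ratios; the longest matching prefix wins, so a
substance-specific row overrides a group row. For ordinary formulations
`total_ome = strength x units/day x days x factor`. Transdermal patches
are handled as rates: their strength is a delivery rate in µg/h, and the
daily OME is `rate x 24 h / 1000 x factor` with the factor expressed per
mg of substance actually delivered (for fentanyl, factor 100, this equals
the familiar 2.4 mg OME per day per µg/h). Methadone's dose-dependent
potency is deliberately flattened to a single configurable factor —
pharmacokinetic modelling is out of scope. Prescriptions with no matching
entry are flagged non-convertible, logged, and by default excluded from
episode construction entirely (the alternative, counting their coverage
days with zero dose, is available as `noncovertible = "coverage_only"`);
the convertible fraction is reported on every run.

### Exposure episodes

A prescription covers the half-open day interval
`[start, start + days_supplied)`; half-open arithmetic internally and
inclusive `end_date` in reports is fixed and documented to prevent
off-by-one drift. Episodes are maximal runs of coverage in which
consecutive covered runs are separated by at most `gap_tolerance` days.
The default tolerance is 0 days — a literal reading of "consecutive" —
and is exposed as a parameter because published episode algorithms differ
precisely here. Three further rules are the package's explicit choices:

* **Overlaps**: days covered by several prescriptions count once toward
  duration, while OME accumulates — dose adds up, time does not. This
  avoids >100% coverage while conserving the dispensed quantity.
* **Denominator**: `mean_daily_ome` divides by episode length (the
  period), not by days-with-supply, matching "average daily dose" over a
  period; with a positive gap tolerance, bridged gap days therefore count
  toward the length and dilute the mean dose.
* **Year boundaries**: intervals are clipped to the calendar year with
  OME pro-rated by the clipped fraction. No episode crosses 31 December,
  so chronic use starting in the last three months of a year cannot be
  identified — a structural limitation of calendar-year analyses that the
  package reproduces by construction.

Classification is then inclusive at both thresholds: an episode of >= 90
days with mean daily dose >= 90 mg OME makes the patient-year chronic
high-dose; any other >= 90-day episode makes it chronic; high-dose takes
precedence, making the classes mutually exclusive. The interval-merge
implementation is tested for exact equality against a brute-force
day-array oracle on randomized patient-years.

### Indirect standardization

A logistic regression (IRLS to deviance tolerance 1e-8, at most 25
iterations — the `stats::glm` default algorithm with tightened control)
predicts each patient's outcome probability from categorical age band,
sex and chronic-disease count (levels 0, 1, 2, 3, >= 4, entered as
categories because that is how such case-mix tables are reported; a
linear term is a trivial user-side change). The practice's expected count
`E` is the sum of its patients' predictions, `O` its observed count, and
the indirectly standardized proportion is `(O/E) x overall proportion`.
Because the model contains an intercept, the maximum-likelihood score
equations force `sum(E) = sum(O)`; the package asserts this to 1e-6
relative on every run, and a test verifies it numerically. With an
intercept-only model the standardized proportion reduces exactly to the
raw proportion, which is how the "unadjusted" analysis is defined.

Two orderings were genuinely open. The model is fitted on **all**
included patients, including those in practices that later turn out to
have zero outcomes — expectations need the full cohort, and exclusion is
purely a reporting step (`standardized_view()` splits the practices and
reports the zero-outcome count separately, to avoid standardized
proportions of zero). And age enters as individual 5-year bands rather
than the 20-year display bands of descriptive tables, because the finer
resolution is available and costs nothing. One documented inconsistency
in the source material — a table footnote mentioning cancer as an
adjustment factor while the cohort definition excludes cancer patients —
is resolved in favour of the cohort definition: there is no cancer
covariate.

### Variation statistics

Two ratio statistics summarise the spread of (positive) practice
proportions: the 95th/5th percentile ratio and the ratio of the mean of
the top 10 to the mean of the bottom 10 practices. Percentiles use linear
interpolation between order statistics (`stats::quantile` type 7)
throughout the package; the convention is stamped into output metadata
because software conventions differ and published ratios cannot be
recomputed from rounded tables to settle which one was used. Both
statistics are scale- and permutation-invariant and are >= 1 by
construction. They are computed on the analyzed set (O >= 1) only.

Even with no true between-practice variation both ratios exceed 1 in
finite samples from sampling noise alone, shrinking toward 1 as practice
size grows — a property the suite checks qualitatively. Conversely, for a
rare outcome with a practice-level random intercept of standard deviation
tau, true practice rates are approximately lognormal and the 95/5 ratio
approaches `exp(2 x 1.645 x tau)`; the suite verifies this closed form at
tau = 0.3 and 0.6 with large practices.

### Funnel plots and overdispersion

The O/E ratio is plotted against `E` with control limits
`1 ± z * sqrt(phi/E)` at the 95% and 99.8% levels (normal-approximation
limits, matching the z-score-based overdispersion machinery and the
smooth funnel curves of standard provider-profiling practice; exact
Poisson limits are a possible extension, not implemented). Practice
z-scores `z = (O - E)/sqrt(E)` are winsorized at their 10% and 90%
quantiles and phi is the mean square of the winsorized scores —
Spiegelhalter's multiplicative variance-inflation estimate. The
adjustment is applied only when `phi > 1 + 2 * sqrt(2/n)`; below the
trigger, limits use phi = 1. The additive random-effects variant is out
of scope. Winsorization never increases the mean square, and inflation
never creates outliers — both are property-tested.

Outlier status is strict: a practice exactly on a limit is in control.
Outlier percentages use the analyzed-practice denominator (practices with
at least one outcome), which is what makes counts like 45 outliers of
361 − 34 plotted practices come out at 13.8%.

### Outlier profiling

For the high-dose outcome, practices are grouped into zero-outcome
practices (never plotted), low outliers and high outliers; in-control
practices are not profiled. Each group is summarised on practice size,
both outcome proportions, low/high-income percentages and urbanicity.
The source material reports means in its methods text but medians and
IQRs in its table; the package emits both, with the median/IQR view
(same quantile convention) as the customary report. Missing covariates
are excluded per field with counts.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions for every calibration test:

| Parameter | Default | Why |
|---|---|---|
| `n_practices` | 361 | 2019-like cohort size |
| size distribution | lognormal(7.803, 0.55) truncated to [500, 13000] | mean list size ~2 838, heavy right tail matching observed min–max ranges |
| age / sex / disease weights | 2019 margins (20–39: 30.6%, male 49.3%, etc.) | descriptive-table emulation |
| `p_cancer`, `p_full_year` | 0.03, 0.95 | plausible exclusion rates; flowchart-style counts, not calibrated to any published figure |
| `base_logit_chronic` | −5.816 | calibrated (by numerical integration over the default case mix and practice-effect distribution) so the marginal any-chronic rate is ~1.59% |
| `base_logit_highdose_given_chronic` | −2.190 | splits chronic use ~1.43% / ~0.16% |
| `tau_practice` | 0.6 | true-rate 95/5 ratio `exp(3.29 x 0.6)` ≈ 7.2, the observed order of magnitude |
| `ses_effect`, `urban_effect` | 8, 0.5 | visible, recoverable coupling of deprivation and urbanicity to prescribing |
| `highdose_margin` | 0.10 | generated daily doses stay 10% away from the 90 mg/day boundary, so boundary behaviour is tested deliberately, never by accident |
| `noise_fraction` | 0.02 | codeine / non-opioid / missing-strength records that the filters must remove |

Design points worth stating explicitly:

* One global seed expands into independent substreams for practices,
  patients, class draws and prescriptions, so enlarging one stage never
  perturbs another, and identical seeds give byte-identical tables.
* Chronic patients get one episode of chained 30-day prescriptions at a
  constant daily dose; with zero noise the episode classifier recovers
  the ground-truth classes exactly, and the suite requires it to.
* The high-dose-given-chronic probability does **not** carry the practice
  random intercept. If it did, high-dose practice rates would scale like
  `exp(2u)` and their spread would be the square of the chronic spread —
  far beyond anything observed. With the conditional independent of `u`,
  both outcomes inherit the same `exp(u)` practice scaling.
* Mean *list* size is calibrated to 2 838; after the patient filters
  (cancer, part-year registration) the included mean is ~5–8% lower. The
  generator targets the list because the patient filters are the
  pipeline's own job.
* SES and urbanicity are linear in `u` with Gaussian noise — the simplest
  mechanism that reproduces the observed direction of association
  (high prescribers poorer and more urban) for recovery tests.

What the generator does **not** emulate: multi-year patient continuity,
within-practice prescriber effects, seasonal prescribing, correlated
case-mix composition across practices, dose tapering, and realistic ATC
market shares. Passing tests therefore demonstrate that the pipeline's
logic is correct under its stated assumptions, not that real prescribing
data meet those assumptions.

## Numerical conventions and degenerate inputs

* Quantiles: type-7 linear interpolation everywhere, stamped in outputs.
* Rounding for display: half away from zero at render time only; all
  stored tables keep full precision, and a self-consistency audit
  recomputes every printed percentage from the counts in the same table.
* Outlier tie-break: strictly outside a limit.
* Percentile ratios warn below 20 practices; top-10/bottom-10 ratios
  require at least 20 and degrade to `NA` (with a warning) inside
  `variation_table()`.
* Degenerate fits: an outcome with zero events (or zero non-events)
  errors; empty or constant covariate levels are dropped with a warning;
  non-convergence and |coefficient| > 15 flag the model rather than fail
  the run.
* Empty cohorts produce all-zero descriptive tables without division
  errors; an empty practice-quality table filters to an empty set.

## Scale of the validation suite

The test suite runs the episode oracle on 1 000 randomized patient-years;
funnel coverage under a homogeneous null on 3 replicates of 361 practices
x 2 838 patients (tolerances are 3 Monte-Carlo standard errors at the
pooled size); closed-form variation recovery on 380 practices x 10 000
patients per tau; and the SES direction-of-association sign test on 20
replicates of 150 practices x 2 000 patients. Calibration-sensitive
checks draw outcome classes directly from the generative model and use
the intercept-only standardization path, which is exactly the unadjusted
analysis; the full prescription-level path is exercised end-to-end by the
recovery and pipeline tests at moderate cohort sizes.

## Known limitations

* Episode rules beyond the 90-day/90-mg definitions (gap tolerance,
  overlap handling, pro-rating) are this package's explicit
  reconstruction of under-specified published practice; all are
  configurable, none can be claimed to match any particular study's
  unpublished algorithm.
* Normal-approximation funnel limits are rough for expected counts below
  ~5; the high-dose outcome sits near that regime at realistic practice
  sizes, which also inflates its finite-sample variation ratios above
  the lognormal closed form.
* The OME table is a curated transcription of published equianalgesic
  ratios; institutional tables differ (notably for methadone and
  transdermal buprenorphine), so the table is data, overridable per run.
* No shrinkage or hierarchical estimation: O/E ratios of small practices
  are noisy by design, which is precisely what the funnel's widening
  limits represent.
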