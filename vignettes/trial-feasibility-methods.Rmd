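---
title: "Methods: estimating a rare-disease trial pool from linked EHRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating a rare-disease trial pool from linked EHRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialpool)
```

`trialpool` estimates how many patients with a rare disease could, in
principle, be recruited to a clinical trial, using linked primary- and
secondary-care electronic health records. This vignette records the
model, the conventions, and the design choices — including the ones
that were genuinely open — in enough detail that a reader can predict
the package's behaviour on any input.

## The estimation problem

Three quantities are chained together:

1. an **incidence rate** for the index disease, crude and by five-year
   age band, from incident cases and person-time in an observed panel;
2. a **national projection**: band rates applied to a national
   population table over the study window, giving the expected number
   of new cases nationally;
3. a **partition of that pool** by recruitment status — derived from
   which treatment cautions each observed case carries and how a panel
   of clinicians graded each caution — and by pre-existing dementia,
   which signals the need for an alternative consent process.

Counts and denominators come from the observed panel; only the final
proportions are applied to the projected national pool.

## Conventions that drive every date computation

- **Imputed birthdate.** Patients carry a year of birth only. 1 July of
  that year is imputed everywhere (`imputed_birthdate()`), which is
  deterministic and unbiased at mid-year. All ages are completed years
  against that date.
- **Calendar-month arithmetic with day clamping.** "12 months after"
  means the same day-of-month 12 months on, clamped to the month end
  (2014-02-28 + 12 months = 2015-02-28). This matches common EHR-study
  practice and is deterministic.
- **Person-time** is `end − start` in days divided by 365.25; the end
  day itself does not contribute.
- **Age bands** run 18–19, 20–24, …, 90–94, 95+. The top band is open
  so that very old patients never fall outside the scheme; the bottom
  band is two years wide because only adults are observed.

## Observation periods and incident cases

Follow-up for incidence starts at the latest of: study start, 12 months
after the current registration date, the practice up-to-standard date,
and the 18th birthday; it ends at the earliest of: study end, death,
transfer out, last collection date, and the linkage date. The 12-month
registration lag exists because diagnoses recorded at registration are
frequently historic: without the lag, prevalent disease inflates
incidence.

A patient's index date is the first-ever disease code across both care
settings. A same-day tie between a primary-care and a hospital record is
resolved to primary care; the choice is arbitrary but fixed, and the
source is carried in the output so sensitivity to the tie-break is
inspectable. A patient whose first-ever code precedes their observation
period is prevalent and is never incident, regardless of later codes.

**Prevalent person-time (open choice).** Whether prevalent patients
should contribute denominator time is not dictated by the definitions
above. The pipeline default (`censor_at_first_code = TRUE`) censors
incident cases at their index date and leaves prevalent patients' full
follow-up in the denominator; switching it off leaves all follow-up
uncensored. With a disease as rare as the intended use case the two
differ by a fraction of a percent; the setting used is written to the
run log.

## Exact Poisson intervals

Rates are events over person-years scaled to 100,000. Intervals are the
exact (Garwood) chi-square inversion: with `x` events, the count-scale
bounds are `qchisq(α/2, 2x)/2` and `qchisq(1−α/2, 2x+2)/2` (lower bound
0 when `x = 0`), divided by person-time. The exact method matters here:
at 237 events the normal approximation shifts the lower rate bound from
7.4 to 7.3 per 100,000 person-years at the same person-time, so the
approximation is not an acceptable substitute when comparing against
published intervals. The test suite pins the implementation against an
independent numerical inversion of the Poisson CDF to 10⁻⁶ relative
tolerance.

**Projection interval (open choice).** The interval for the national
projection sums the band-wise bounds (rate bound × band population ×
years / 10⁵). This is deliberately conservative — bands are treated as
moving together rather than independently — and is wider than a
variance-propagated interval. No age-standardisation or trend
modelling is attempted.

**Pool partitioning.** Status proportions among observed cases are
applied to the projected total and rounded half away from zero
(`pool_sizes()`); dementia pools are the status pools times the
within-status dementia share. The projected total to partition is an
explicit argument, so a rounded headline figure can be used in place of
the point estimate when reproducing published tables. Percentages are
reported at 1 decimal place, also half away from zero; note that a
cross-tabulation of 34 dementia cases among 237 is 14.345…%, which this
package reports as 14.3%.

## Eligibility windows

Each caution couples a code list to a lookback window relative to the
index date:

- `ANY_BEFORE`: any matching code in `[up_to_standard_date, index)`.
  The up-to-standard bound exists because records before it are not
  research quality.
- `MONTHS_BEFORE`/`YEARS_BEFORE` of length *k*: any matching code in
  `[index − k, index)` **and** at least 12 months after the current
  registration date. The guard removes historic events re-entered on
  joining a new practice, which would otherwise be dated as recent.

Both windows are half-open at the index date: a code on the index date
never qualifies, since the caution must pre-exist the diagnosis.
Dementia uses `ANY_BEFORE` semantics. Codes whose text merely states a
*history of* a condition date the recording, not the event, so they are
removed from time-limited cautions (`strip_history_codes()`); they are
marked by an explicit CSV column rather than inferred from code text,
because the original curation was a manual review that cannot be
reproduced algorithmically. ICD-10 codes match on a normalized form
(dot stripped, case-insensitive), Read and product codes exactly;
3-character ICD-10 prefix matching is available behind a flag
(`icd10_prefix`) but off by default, since exact matching is the
stricter and more auditable choice.

## Consensus rule

Each grader rates each condition very likely / somewhat likely /
unlikely to lead to exclusion. Per condition, the branches are checked
most restrictive first: recruitment **unlikely** if > 50% graded very
likely; else **with caution** if > 50% graded very or somewhat likely;
else **possible** if > 50% graded unlikely. With an odd grader count
exactly one branch fires (the test suite asserts this over every
composition of 13 grades). The branch order matters: a condition with a
strict very-likely majority is never demoted by its combined count.
With an even grader count all three branches can fail; the fallback is
**with caution** — the conservative middle ground — with a warning. A
patient's status is the most restrictive among their present cautions;
no caution means possible.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a linked UK primary-care
panel: practices with up-to-standard and last-collection dates,
patients with a year of birth, registration/transfer/death dates and a
research-quality flag, and dated coded events in seven source tables
(clinical, referral, test, therapy, immunisation, hospital diagnoses,
hospital procedures).

Defaults are chosen once to be realistic for the intended setting, and
are not tuned to any test outcome:

- **Study window** 2015-01-01 to 2017-12-31 (three years), linkage date
  2018-03-31.
- **Age structure**: adult population shares per five-year band
  (`default_age_distribution()`), weighted like a national adult
  population with a thin 95+ tail.
- **Planted incidence** (`default_planted_incidence()`): steeply
  age-rising, from ≈ 0.2 per 100,000 person-years in young adults to
  100 in the 95+ band — the canonical shape for a blistering disease of
  the very old. Arrivals are an age-inhomogeneous Poisson process over
  each patient's registered adult time, simulated by thinning a
  homogeneous process at the maximum band rate, which is exact for
  piecewise-constant rates. The first arrival is the onset.
- **Dual recording**: an incident diagnosis lands in primary care only
  (0.6), hospital only (0.2), or both (0.2); when both, the hospital
  record is dated `hospital_offset_days` (default 0) after the
  primary-care record, so the same-day source tie-break is exercised
  by default.
- **Registration churn** (`annual_registration_turnover`, default
  0.08/year) drives both tenure at the study start (exponential) and
  transfer-out; **mortality** is a Gompertz-style hazard
  `5e-5 · exp(0.085 · age)` capped at 0.5/year, enough to make elderly
  follow-up realistically right-censored without modelling a full life
  table.
- **Comorbidities** (`default_caution_profiles()`): independent
  Bernoulli carriage per condition with lifetime prevalences of the
  order seen in elderly populations (hypertension 0.55 down to
  systemic sclerosis 0.002); onset is uniform over the registered adult
  record. Dementia carriage is by age band at the end of the record,
  with onset in the last ten years of follow-up. No correlation
  structure between conditions is modelled — the generator makes no
  claim about comorbidity clustering, so multimorbidity-driven
  quantities (e.g. the share of cases with ≥ 2 cautions) should not be
  read off synthetic runs as if they were real-world estimates.

Every planted onset is returned as ground truth, which is what the
tests compare recovered index dates and caution hits against. Identical
configuration and seed reproduce the tables byte for byte.

**What passing tests show — and what they do not.** The synthetic data
validate the *mechanics*: interval construction, window matching,
person-time splitting, estimator coverage. They do not validate the
clinical code algorithm (code lists are taken as given), recording
completeness, or the joint distribution of comorbidities in real
records, so agreement on synthetic data is necessary, not sufficient,
for agreement on licensed microdata.

## Numerical and degenerate-input behaviour

- Bands with zero person-time report `NA` rates (undefined, not zero)
  and are dropped from projections with a message listing them.
- Zero events give a zero rate with a zero lower bound and a positive
  exact upper bound.
- Empty period lists, zero-row hit tables, and caution-free patients
  are all well-defined (all-zero person-time table, empty hit set,
  status possible).
- A cohort with no incident cases stops the pipeline with a stage-named
  error rather than emitting an empty report.
- Duplicate code-list rows collapse with a warning; inconsistent
  condition metadata, unknown coding systems, and missing window
  lengths are errors naming the file and row.

## Problem sizes used in validation

The test suite works at sizes chosen to make each check informative:
band-rate recovery uses a 200,000-patient panel at a planted flat rate
of 300 per 100,000 person-years, so that multiple bands exceed 50
expected events; interval coverage uses a fixed 1.3-million-patient
panel (≈ 2.2 million person-years) with disease arrivals re-planted at
8.4 per 100,000 person-years across 200 replicates, checked by an exact
binomial test against the nominal 95% at α = 0.01; window matching is
cross-checked against a brute-force row scan over 1,000 randomized
window/date configurations on 200-patient cohorts. Rates this rare make
per-replicate case counts small (~190), which is precisely the regime
the exact interval exists for.

## Known limitations

- Caution severity is invisible to code-based screening, so the
  recruitment-status partition is a floor on exclusions, not a
  ceiling; clinicians will exclude some "with caution" patients.
- Cautions cannot be attributed to (or disentangled from) prior
  treatment with the comparator drug itself.
- Read/ICD-10 vocabularies are not mapped to each other and SNOMED is
  unsupported; bundled code lists are synthetic placeholders with the
  documented schema.
- Each registration is treated as independent; patients transferring
  between practices do not carry record continuity.
- The projection inherits whatever bias the panel's age-band rates
  carry; no standardisation is applied.
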