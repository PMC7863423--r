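# trialpool

Trial-feasibility estimation from linked electronic health records.

Planning a clinical trial in a rare disease starts with a question that is
surprisingly hard to answer: *are there enough eligible patients in the
country to recruit at all?* `trialpool` implements an EHR-based answer for
diseases phenotyped from linked primary-care (Read-coded) and hospital
(ICD-10/OPCS-coded) records, developed around the worked case of bullous
pemphigoid — a rare autoimmune blistering disease of older people — and a
hypothetical trial whose comparator arm is oral prednisolone.

The pipeline:

1. **Observation periods.** For each research-quality patient, follow-up
   runs from the latest of the study start, 12 months after registration
   (a lag that keeps historically recorded disease from masquerading as
   incident), the practice's up-to-standard date, and the 18th birthday,
   to the earliest of study end, death, transfer out, last data
   collection, and the linkage date.
2. **Incident cases.** A patient's index date is their first-ever disease
   code across both care settings; they are incident if it falls inside
   their observation period and ≥ 1 year after registration.
3. **Incidence.** Crude and five-year-age-band rates
   λ̂ = events / person-years × 10⁵, with exact (Garwood) Poisson
   confidence intervals from the chi-square inversion

   CI(x) = [ χ²(α/2, 2x)/2 , χ²(1−α/2, 2x+2)/2 ] / PY × 10⁵,

   and extrapolation of band rates to a national population table to give
   the expected national case pool over the study window.
4. **Eligibility screening.** Each case is screened against condition
   code lists with per-condition lookback windows (e.g. varicella zoster
   vaccination in the 3 months before the index date; osteoporosis any
   time before), with a 12-month post-registration guard on time-limited
   windows and an up-to-standard lower bound on open-ended ones.
5. **Consensus recruitment status.** Clinician survey grades
   (very / somewhat / unlikely to exclude) are aggregated per condition
   by strict majority (> 50%), checked most-restrictive-first; a
   patient's status is the most restrictive status among their cautions.
6. **Feasibility report.** Cases are cross-classified by recruitment
   status × pre-existing dementia (any dementia code strictly before the
   index date, a proxy for needing an alternative consent process), and
   the observed proportions are applied to the extrapolated national
   pool.

A synthetic linked-EHR generator with plantable age-specific incidence,
comorbidity prevalence, and dual-source recording makes every stage
testable without access-restricted data.

## Worked example

```r
library(trialpool)

cfg <- sim_config(n_practices = 20, patients_per_practice = 10000, seed = 42L)
run <- run_pipeline(cfg)

glance(run$rates)
#> # A tibble: 1 × 5
#>   events person_years  rate ci_low ci_high
#>    <int>        <dbl> <dbl>  <dbl>   <dbl>
#> 1     12      232233.  5.17   2.67    9.03

tidy(run$report)
#> # A tibble: 3 × 7
#>   status           n   pct dementia_n dementia_pct  pool dementia_pool
#>   <fct>        <int> <dbl>      <int>        <dbl> <int>         <int>
#> 1 POSSIBLE         9    75          0            0  5926             0
#> 2 WITH_CAUTION     3    25          0            0  1975             0
#> 3 UNLIKELY         0     0          0           NA     0             0
```

Twelve incident cases arise in 232,233 person-years of follow-up — a
crude rate of 5.2 (95% CI 2.7 to 9.0) per 100,000 person-years — and
extrapolating the age-specific rates to the bundled example population
table projects a national three-year pool of ≈ 7,900 new cases, of which
≈ 5,900 sit in the "recruitment possible" stratum. The small case count
from a 200,000-patient panel is the point: it is exactly this scarcity
that makes feasibility estimation worth doing before committing to a
trial. `autoplot(run$rates)`, `autoplot(run$report)` and
`plot_caution_summary(run$caution_table)` draw the standard figures.

External tables with the same schema (see `read_cohort()`,
`read_codelists()`, `read_survey()`, `read_population()`) can be
substituted for the simulated ones via `run_pipeline(tables = ...)`;
the bundled code lists use short synthetic code values, and licensed
Read/ICD-10 lists are a drop-in replacement.

## Package layout

- `R/synthetic.R` — synthetic cohort generator (`sim_config()`,
  `generate_cohort()`, `plant_disease_events()`)
- `R/codelists.R` — code-list loading, validation, history-code
  stripping
- `R/cohort.R` — observation periods, person-time by age band, incident
  cases
- `R/incidence.R` — exact Poisson intervals, rates, national
  extrapolation, pool partitioning
- `R/eligibility.R` — caution window matching, dementia flags
- `R/consensus.R` — survey-grade aggregation and patient status
- `R/report.R`, `R/pipeline.R`, `R/plots.R` — the feasibility report,
  orchestration, and figures

See the methods vignette (`vignettes/trial-feasibility-methods.Rmd`) for
the modelling choices, defaults, and limitations.
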