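Package: trialpool
Title: Trial Feasibility Estimation from Linked Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the national pool of potential clinical-trial
    participants for a rare disease from linked primary- and secondary-care
    electronic health records. Builds observation periods and person-time by
    five-year age band, identifies incident cases from clinical code lists,
    estimates crude and age-specific incidence with exact Poisson confidence
    intervals, extrapolates expected case counts to a national population,
    screens cases against treatment cautions within condition-specific
    lookback windows, aggregates clinician survey grades into recruitment
    statuses by majority consensus, and partitions the extrapolated pool by
    recruitment status and pre-existing dementia. Ships a synthetic
    linked-EHR generator with plantable age-specific incidence and
    comorbidity prevalence so every stage is testable without restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
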