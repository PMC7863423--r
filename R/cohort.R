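# Observation periods, person-time by age band, incident cases.

#' Build incidence observation periods
#'
#' For each acceptable patient, follow-up for the incidence calculation
#' starts at the latest of the study start, 12 months after the current
#' registration date, the practice's up-to-standard date, and the
#' patient's 18th birthday; it ends at the earliest of the study end, the
#' death date, the transfer-out date, the practice's last collection date,
#' and the linkage date (missing dates are ignored). Patients whose start
#' is on or after their end contribute no period. Non-acceptable patients
#' are dropped.
#'
#' @param patients Patient tibble (`patient_id`, `practice_id`,
#'   `birth_year`, `current_registration_date`, `transfer_out_date`,
#'   `death_date`, `acceptable`).
#' @param practices Practice tibble (`practice_id`, `up_to_standard_date`,
#'   `last_collection_date`).
#' @param study_start,study_end Study window `Date`s.
#' @param linkage_date Most recent primary/secondary-care linkage `Date`.
#' @return Tibble `patient_id`, `start`, `end` — one row per patient with
#'   a non-empty period.
#' @export
build_observation_periods <- function(patients, practices,
                                      study_start = as.Date("2015-01-01"),
                                      study_end = as.Date("2017-12-31"),
                                      linkage_date = as.Date("2018-03-31")) {
  joined <- patients |>
    filter(.data$acceptable) |>
    inner_join(practices, by = "practice_id")
  start <- pmax(
    study_start,
    add_months(joined$current_registration_date, 12),
    joined$up_to_standard_date,
    imputed_birthdate(joined$birth_year + 18L)
  )
  end <- pmin(
    study_end,
    joined$last_collection_date,
    linkage_date,
    dplyr::coalesce(joined$death_date, study_end),
    dplyr::coalesce(joined$transfer_out_date, study_end)
  )
  tibble(patient_id = joined$patient_id, start = start, end = end) |>
    filter(.data$start < .data$end)
}

#' Split person-time into five-year age bands
#'
#' Each period is cut at the dates the patient crosses a band boundary
#' (1 July birthdays, from the imputed birthdate); each segment
#' contributes its exact day count divided by 365.25. Person-time is
#' `end - start` in days (the end day itself is not counted).
#'
#' @param periods Tibble `patient_id`, `start`, `end`.
#' @param patients Patient tibble providing `birth_year`; every period's
#'   patient must be present.
#' @return Tibble `band` (factor over [age_band_levels()]),
#'   `person_years`, with one row per band (zero where unobserved).
#' @export
person_time_by_band <- function(periods, patients) {
  empty <- tibble(band = factor(age_band_levels(), levels = age_band_levels()),
                  person_years = 0)
  if (nrow(periods) == 0) return(empty)
  missing <- setdiff(periods$patient_id, patients$patient_id)
  if (length(missing) > 0) {
    abort(paste0("person_time_by_band(): unknown patient(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  p <- periods |>
    inner_join(patients |> select("patient_id", "birth_year"), by = "patient_id") |>
    mutate(.row = dplyr::row_number())

  # collect band-boundary birthdays falling strictly inside each period
  cuts <- purrr::map(band_lower_edges()[-1], function(a) {
    cd <- imputed_birthdate(p$birth_year + a)
    keep <- p$start < cd & cd < p$end
    tibble(.row = p$.row[keep], date = cd[keep])
  }) |> list_rbind()

  # within each period the points are start < cuts... < end strictly, so
  # after sorting by (.row, date) a global lead() gives each non-end
  # point's segment end without per-period grouping
  pts <- bind_rows(
    tibble(.row = p$.row, date = p$start, kind = "start"),
    cuts |> mutate(kind = "cut"),
    tibble(.row = p$.row, date = p$end, kind = "end")
  ) |>
    arrange(.data$.row, .data$date) |>
    mutate(seg_end = dplyr::lead(.data$date)) |>
    filter(.data$kind != "end")

  pts <- pts |>
    left_join(p |> select(".row", "birth_year"), by = ".row") |>
    mutate(
      age = age_at(.data$birth_year, .data$date),
      person_years = days_between(.data$date, .data$seg_end) / 365.25
    )
  pts |>
    mutate(band = age_band(.data$age)) |>
    group_by(.data$band, .drop = FALSE) |>
    summarise(person_years = sum(.data$person_years), .groups = "drop")
}

#' Identify incident cases of the index disease
#'
#' A patient's index date is the date of their first-ever disease code
#' across both care settings (primary-care Read/product tables and
#' hospital diagnosis/procedure tables). The patient is an incident case
#' iff that first code falls inside their incidence observation period
#' and at least one year (by default) after their current registration
#' date; the registration lag excludes prevalent disease recorded at
#' registration. A same-day tie between sources resolves to primary care.
#'
#' @param events Event tibble (`patient_id`, `event_date`, `code`,
#'   `coding_system`, `source_table`).
#' @param disease_spec Disease specification from [codelist_spec()]
#'   (role `"disease"`).
#' @param periods Observation periods from [build_observation_periods()].
#' @param patients Patient tibble (for `current_registration_date`,
#'   `birth_year`).
#' @param lag_months Registration lag in calendar months (default 12).
#' @return Tibble `patient_id`, `index_date`, `index_source`
#'   (`"primary_care"`/`"hospital"`), `age_at_index`, `band`.
#' @export
identify_incident_cases <- function(events, disease_spec, periods, patients,
                                    lag_months = 12) {
  if (nrow(disease_spec$codes) == 0) abort("disease code list is empty")
  first_codes <- first_disease_codes(events, disease_spec)
  first_codes |>
    inner_join(periods, by = "patient_id") |>
    inner_join(patients |>
                 select("patient_id", "birth_year", "current_registration_date"),
               by = "patient_id") |>
    filter(
      .data$index_date >= .data$start,
      .data$index_date <= .data$end,
      .data$index_date >= add_months(.data$current_registration_date, lag_months)
    ) |>
    mutate(
      age_at_index = age_at(.data$birth_year, .data$index_date),
      band = age_band(.data$age_at_index)
    ) |>
    select("patient_id", "index_date", "index_source", "age_at_index", "band") |>
    arrange(.data$patient_id)
}

# earliest disease code per patient across both settings; primary care
# wins a same-day tie
first_disease_codes <- function(events, disease_spec) {
  matched <- match_events(events, disease_spec$codes)
  if (nrow(matched) == 0) {
    return(tibble(patient_id = character(), index_date = as.Date(character()),
                  index_source = character()))
  }
  matched |>
    mutate(index_source = ifelse(
      .data$source_table %in% c("hes_diagnosis", "hes_procedure"),
      "hospital", "primary_care"
    )) |>
    group_by(.data$patient_id) |>
    arrange(.data$event_date, .data$index_source != "primary_care", .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("patient_id", index_date = "event_date", "index_source")
}

# semi-join events to a code tibble on normalized (code, system);
# optionally match ICD-10 on the 3-character prefix
match_events <- function(events, codes, icd10_prefix = FALSE) {
  ev <- events |>
    mutate(.norm = normalize_code(.data$code, .data$coding_system))
  cd <- codes |>
    mutate(.norm = normalize_code(.data$code, .data$system)) |>
    select(.norm_cd = ".norm", system_cd = "system")
  exact <- ev |>
    inner_join(cd, by = c(.norm = ".norm_cd", coding_system = "system_cd"),
               relationship = "many-to-many") |>
    distinct()
  if (icd10_prefix) {
    icd <- cd |> filter(.data$system_cd == "ICD10") |>
      mutate(.pref = substr(.data$.norm_cd, 1, 3)) |> distinct(.data$.pref)
    pref <- ev |>
      filter(.data$coding_system == "ICD10",
             substr(.data$.norm, 1, 3) %in% icd$.pref)
    exact <- bind_rows(exact, pref) |> distinct()
  }
  exact |> select(-".norm")
}
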