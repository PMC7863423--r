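# Screening incident cases against treatment cautions within their
# condition-specific lookback windows, and pre-existing dementia.

# lower edge of a caution's lookback window relative to an index date;
# NA for ANY_BEFORE (bounded instead by the up-to-standard date)
window_start <- function(index_date, window_kind, window_length) {
  switch(window_kind,
    ANY_BEFORE = as.Date(NA),
    MONTHS_BEFORE = add_months(index_date, -window_length),
    YEARS_BEFORE = add_months(index_date, -12L * window_length),
    abort(paste0("unknown window kind '", window_kind, "'"))
  )
}

#' Match one caution against one patient's events
#'
#' For an any-time-before caution, a hit is any matching code dated in
#' `[up_to_standard_date, index_date)`. For a time-limited caution of k
#' months/years, a hit is any matching code dated in
#' `[index_date - k, index_date)` that is also at least 12 months after
#' the current registration date (guarding against historic events
#' re-entered on registration with a new practice). The window is
#' half-open at the index date: a code on the index date itself never
#' qualifies (the condition must pre-exist the diagnosis). The earliest
#' qualifying date is reported.
#'
#' @param events Events for one patient.
#' @param spec Caution specification ([codelist_spec()]).
#' @param index_date Index date of the patient's incident diagnosis.
#' @param registration_date Current registration date.
#' @param up_to_standard_date Practice up-to-standard date.
#' @param icd10_prefix Match ICD-10 on 3-character prefixes (default
#'   exact normalized match).
#' @return One-row tibble `condition`, `earliest_date`, `window_kind`, or
#'   a zero-row tibble when no code qualifies.
#' @export
match_caution <- function(events, spec, index_date, registration_date,
                          up_to_standard_date, icd10_prefix = FALSE) {
  hits <- match_events(events, spec$codes, icd10_prefix = icd10_prefix)
  lo <- window_start(index_date, spec$window_kind, spec$window_length)
  if (spec$window_kind == "ANY_BEFORE") {
    ok <- hits$event_date >= up_to_standard_date & hits$event_date < index_date
  } else {
    guard <- add_months(registration_date, 12)
    ok <- hits$event_date >= lo & hits$event_date < index_date &
      hits$event_date >= guard
  }
  if (!any(ok)) {
    return(tibble(condition = character(), earliest_date = as.Date(character()),
                  window_kind = character()))
  }
  tibble(
    condition = spec$condition,
    earliest_date = min(hits$event_date[ok]),
    window_kind = spec$window_kind
  )
}

#' Caution hits for every incident case
#'
#' Applies every caution's code list and lookback window to every
#' incident case, across all primary-care source tables (clinical,
#' referral, test, therapy, immunisation) and both hospital tables.
#'
#' @param cases Incident cases ([identify_incident_cases()]).
#' @param events Full event tibble.
#' @param collection A `codelist_collection`.
#' @param patients Patient tibble.
#' @param practices Practice tibble.
#' @param icd10_prefix Match ICD-10 on 3-character prefixes.
#' @return Long tibble `patient_id`, `condition`, `earliest_date`,
#'   `window_kind` — one row per (case, caution present).
#' @export
caution_profile <- function(cases, events, collection, patients, practices,
                            icd10_prefix = FALSE) {
  meta <- case_meta(cases, patients, practices)
  ev_by_patient <- events |>
    filter(.data$patient_id %in% cases$patient_id) |>
    group_by(.data$patient_id)
  keys <- group_keys(ev_by_patient)$patient_id
  ev_split <- group_split(ev_by_patient)
  names(ev_split) <- keys
  empty_events <- events[0, ]

  purrr::map(caution_names(collection), function(cond) {
    spec <- codelist_spec(collection, cond)
    purrr::pmap(
      list(meta$patient_id, meta$index_date,
           meta$current_registration_date, meta$up_to_standard_date),
      function(pid, idx, reg, uts) {
        ev <- ev_split[[pid]] %||% empty_events
        match_caution(ev, spec, idx, reg, uts, icd10_prefix = icd10_prefix) |>
          mutate(patient_id = pid)
      }
    ) |> list_rbind()
  }) |>
    list_rbind() |>
    select("patient_id", "condition", "earliest_date", "window_kind") |>
    arrange(.data$patient_id, .data$condition)
}

case_meta <- function(cases, patients, practices) {
  cases |>
    inner_join(patients |>
                 select("patient_id", "practice_id", "current_registration_date"),
               by = "patient_id") |>
    inner_join(practices |> select("practice_id", "up_to_standard_date"),
               by = "practice_id")
}

#' Per-condition caution counts among incident cases
#'
#' Summarises [caution_profile()] hits into the per-condition count and
#' percentage layout of a caution table: one row per caution, `n` cases
#' with a qualifying record and the percentage of all cases (1 decimal
#' place, half away from zero).
#'
#' @param hits Output of [caution_profile()].
#' @param cases The incident cases screened.
#' @param collection The `codelist_collection` (for the full caution list
#'   and statuses; cautions with zero hits are kept).
#' @return Tibble `condition`, `n`, `pct`, `status`.
#' @export
caution_summary <- function(hits, cases, collection) {
  total <- nrow(cases)
  counts <- hits |> count(.data$condition)
  collection$conditions |>
    filter(.data$role == "caution") |>
    select("condition", "status") |>
    left_join(counts, by = "condition") |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      pct = round_half_away(100 * .data$n / total, 1)
    ) |>
    select("condition", "n", "pct", "status")
}

#' Flag pre-existing dementia among incident cases
#'
#' A case has pre-existing dementia iff any dementia code is dated
#' strictly before the index date (any-time-before semantics, bounded
#' below by the practice's up-to-standard date). Codes on or after the
#' index date do not count.
#'
#' @param cases Incident cases.
#' @param events Full event tibble.
#' @param dementia_spec Dementia specification
#'   (`codelist_spec(collection, role = "dementia")`).
#' @param patients,practices Patient and practice tibbles.
#' @param icd10_prefix Match ICD-10 on 3-character prefixes.
#' @return Tibble `patient_id`, `dementia` (logical), one row per case.
#' @export
dementia_flags <- function(cases, events, dementia_spec, patients, practices,
                           icd10_prefix = FALSE) {
  meta <- case_meta(cases, patients, practices)
  matched <- match_events(events |> filter(.data$patient_id %in% cases$patient_id),
                          dementia_spec$codes, icd10_prefix = icd10_prefix)
  flagged <- matched |>
    inner_join(meta |> select("patient_id", "index_date", "up_to_standard_date"),
               by = "patient_id") |>
    filter(.data$event_date >= .data$up_to_standard_date,
           .data$event_date < .data$index_date) |>
    distinct(.data$patient_id)
  cases |>
    transmute(.data$patient_id,
              dementia = .data$patient_id %in% flagged$patient_id)
}
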