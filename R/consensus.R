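# Aggregating clinician survey grades into recruitment statuses, and
# rolling condition statuses up to a per-patient status.

SURVEY_GRADES <- c("VERY_LIKELY", "SOMEWHAT_LIKELY", "UNLIKELY")

#' Classify one condition from survey grades
#'
#' Strict-majority consensus over graders' three-level likelihood that a
#' condition would exclude a patient from the trial. Branches are checked
#' most-restrictive first: `UNLIKELY` (to recruit) iff strictly more than
#' half graded `VERY_LIKELY` to exclude; otherwise `WITH_CAUTION` iff
#' strictly more than half graded `VERY_LIKELY` or `SOMEWHAT_LIKELY`
#' combined; otherwise `POSSIBLE` iff strictly more than half graded
#' `UNLIKELY` to exclude. With an odd number of graders exactly one
#' branch fires; an even-count tie (no category clears 50%) falls back to
#' `WITH_CAUTION` with a warning, the conservative middle ground.
#'
#' @param grades Character vector of grades (`VERY_LIKELY`,
#'   `SOMEWHAT_LIKELY`, `UNLIKELY`), one per grader.
#' @return One of `"POSSIBLE"`, `"WITH_CAUTION"`, `"UNLIKELY"`.
#' @export
classify_condition <- function(grades) {
  bad <- setdiff(unique(grades), SURVEY_GRADES)
  if (length(bad) > 0) abort(paste0("unknown survey grade '", bad[1], "'"))
  if (length(grades) == 0) abort("classify_condition(): no grades supplied")
  n <- length(grades)
  very <- sum(grades == "VERY_LIKELY")
  combined <- very + sum(grades == "SOMEWHAT_LIKELY")
  unlik <- sum(grades == "UNLIKELY")
  if (very > n / 2) return("UNLIKELY")
  if (combined > n / 2) return("WITH_CAUTION")
  if (unlik > n / 2) return("POSSIBLE")
  warn("no category graded by > 50% of graders; falling back to WITH_CAUTION")
  "WITH_CAUTION"
}

#' Classify every condition in a survey table
#'
#' @param survey Tibble `grader_id`, `condition`, `grade` — one row per
#'   (grader, condition); a duplicated grader for a condition is an error.
#' @return Tibble `condition`, `n_graders`, `status`.
#' @export
classify_conditions <- function(survey) {
  dup <- survey |> count(.data$condition, .data$grader_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("grader '", dup$grader_id[1], "' graded '", dup$condition[1],
                 "' more than once"))
  }
  survey |>
    group_by(.data$condition) |>
    summarise(n_graders = dplyr::n(),
              status = classify_condition(.data$grade),
              .groups = "drop")
}

#' Roll condition statuses up to a per-patient recruitment status
#'
#' A patient's status is the most restrictive status among the cautions
#' present in their record (`UNLIKELY` > `WITH_CAUTION` > `POSSIBLE`);
#' patients with no caution, or only cautions unlikely to lead to
#' exclusion, are `POSSIBLE`.
#'
#' @param cases Incident cases (supplies the full patient list, so
#'   hit-free patients are classified too).
#' @param hits Caution hits ([caution_profile()]).
#' @param statuses Tibble `condition`, `status` mapping every condition
#'   that can appear in `hits`; a hit with no status is an error.
#' @return Tibble `patient_id`, `status` (factor
#'   POSSIBLE < WITH_CAUTION < UNLIKELY).
#' @export
classify_patients <- function(cases, hits, statuses) {
  missing <- setdiff(unique(hits$condition), statuses$condition)
  if (length(missing) > 0) {
    abort(paste0("no recruitment status for condition(s): ",
                 paste(missing, collapse = ", ")))
  }
  ranked <- if (nrow(hits) == 0) {
    tibble(patient_id = character(), rank = integer())
  } else {
    hits |>
      inner_join(statuses |> select("condition", "status"), by = "condition") |>
      mutate(rank = match(.data$status, RECRUITMENT_LEVELS)) |>
      group_by(.data$patient_id) |>
      summarise(rank = max(.data$rank), .groups = "drop")
  }
  cases |>
    select("patient_id") |>
    left_join(ranked, by = "patient_id") |>
    mutate(status = factor(RECRUITMENT_LEVELS[dplyr::coalesce(.data$rank, 1L)],
                           levels = RECRUITMENT_LEVELS)) |>
    select("patient_id", "status")
}

#' Read a survey-response CSV
#'
#' @param path CSV with columns `grader_id`, `condition`, `grade`.
#' @return Tibble suitable for [classify_conditions()].
#' @export
read_survey <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    grader_id = readr::col_character(),
    condition = readr::col_character(),
    grade = readr::col_character()
  ))
}
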