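# The feasibility report: incident cases cross-classified by recruitment
# status and pre-existing dementia, with extrapolated national pools.

#' Build the trial-feasibility report
#'
#' Cross-classifies the incident cases by recruitment status and
#' pre-existing dementia, and applies the observed proportions to an
#' extrapolated national case total: each status pool is the total times
#' the status share (rounded half away from zero), and each status's
#' dementia pool is that pool times the within-status dementia share.
#' Percentages are reported to 1 decimal place, half away from zero.
#'
#' @param cases Incident cases ([identify_incident_cases()]).
#' @param patient_statuses Tibble `patient_id`, `status`
#'   ([classify_patients()]); every case needs a status.
#' @param dementia Tibble `patient_id`, `dementia`
#'   ([dementia_flags()]); every case needs a flag.
#' @param projection_total Extrapolated national case count to partition
#'   (e.g. `extrapolate_cases()$total`, or a rounded headline figure —
#'   the choice is the caller's and is recorded in the report).
#' @return List of class `feasibility_report`: `by_status` tibble
#'   (`status`, `n`, `pct`, `dementia_n`, `dementia_pct`, `pool`,
#'   `dementia_pool`), `total_cases`, `dementia_total`,
#'   `dementia_total_pct`, `projection_total`.
#' @export
build_report <- function(cases, patient_statuses, dementia, projection_total) {
  if (nrow(cases) == 0) abort("build_report(): no incident cases")
  tab <- cases |>
    select("patient_id") |>
    left_join(patient_statuses, by = "patient_id") |>
    left_join(dementia, by = "patient_id")
  if (any(is.na(tab$status))) abort("build_report(): case(s) without a status")
  if (any(is.na(tab$dementia))) {
    abort("build_report(): case(s) without a dementia flag")
  }
  total <- nrow(tab)
  by_status <- tab |>
    group_by(status = factor(.data$status, levels = RECRUITMENT_LEVELS),
             .drop = FALSE) |>
    summarise(n = dplyr::n(), dementia_n = sum(.data$dementia),
              .groups = "drop") |>
    mutate(
      pct = round_half_away(100 * .data$n / total, 1),
      dementia_pct = ifelse(.data$n > 0,
                            round_half_away(100 * .data$dementia_n / .data$n, 1),
                            NA_real_)
    )
  pools <- pool_sizes(projection_total, setNames(by_status$n, by_status$status),
                      total)
  by_status <- by_status |>
    mutate(
      pool = pools$pool,
      dementia_pool = ifelse(
        .data$n > 0,
        as.integer(round_half_away(.data$pool * .data$dementia_n / .data$n)),
        0L
      )
    ) |>
    select("status", "n", "pct", "dementia_n", "dementia_pct",
           "pool", "dementia_pool")
  structure(
    list(
      by_status = by_status,
      total_cases = total,
      dementia_total = sum(by_status$dementia_n),
      dementia_total_pct = round_half_away(
        100 * sum(by_status$dementia_n) / total, 1),
      projection_total = projection_total
    ),
    class = "feasibility_report"
  )
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("<feasibility_report>: ", x$total_cases, " incident cases; ",
      x$dementia_total, " (", x$dementia_total_pct,
      "%) with pre-existing dementia\n", sep = "")
  cat("projection total: ", format(x$projection_total, big.mark = ","),
      "\n", sep = "")
  print(x$by_status)
  invisible(x)
}

#' Tidy a feasibility report into its status table
#'
#' @param x A `feasibility_report`.
#' @param ... Unused.
#' @return The `by_status` tibble: one row per recruitment status with
#'   case counts, percentages, dementia cross-tab, and extrapolated
#'   pools.
#' @method tidy feasibility_report
#' @export
tidy.feasibility_report <- function(x, ...) x$by_status

#' One-row summary of a feasibility report
#'
#' @param x A `feasibility_report`.
#' @param ... Unused.
#' @return One-row tibble: total cases, dementia total and percentage,
#'   projection total, and the three status pools.
#' @method glance feasibility_report
#' @export
glance.feasibility_report <- function(x, ...) {
  p <- setNames(x$by_status$pool, x$by_status$status)
  tibble(
    total_cases = x$total_cases,
    dementia_total = x$dementia_total,
    dementia_total_pct = x$dementia_total_pct,
    projection_total = x$projection_total,
    pool_possible = p[["POSSIBLE"]],
    pool_with_caution = p[["WITH_CAUTION"]],
    pool_unlikely = p[["UNLIKELY"]]
  )
}

#' Tidy incidence estimates
#'
#' @param x An `incidence_estimates` tibble.
#' @param ... Unused.
#' @return The estimates as a plain tibble (band, events, person_years,
#'   rate and CI per 100,000 person-years).
#' @method tidy incidence_estimates
#' @export
tidy.incidence_estimates <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "incidence_estimates")
  out
}

#' One-row crude-rate summary of incidence estimates
#'
#' @param x An `incidence_estimates` tibble.
#' @param ... Unused.
#' @return One-row tibble with the crude events, person-years, rate and
#'   confidence bounds.
#' @method glance incidence_estimates
#' @export
glance.incidence_estimates <- function(x, ...) {
  crude <- x |> filter(.data$band == "CRUDE")
  tibble(events = crude$events, person_years = crude$person_years,
         rate = crude$rate, ci_low = crude$ci_low, ci_high = crude$ci_high)
}

#' Serialise a feasibility report to JSON
#'
#' @param report A `feasibility_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "feasibility_report"))
  out <- list(
    schema = "trialpool/feasibility_report/v1",
    total_cases = report$total_cases,
    dementia_total = report$dementia_total,
    dementia_total_pct = report$dementia_total_pct,
    projection_total = report$projection_total,
    by_status = report$by_status |> mutate(status = as.character(.data$status))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
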