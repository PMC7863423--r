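# End-to-end orchestration: simulate (or load) -> observation periods ->
# person-time -> incident cases -> incidence & extrapolation ->
# eligibility -> consensus -> feasibility report.

#' Run the full trial-feasibility pipeline
#'
#' Executes every stage over a synthetic cohort (generated from `config`)
#' or externally supplied tables of the same schema, and returns the
#' feasibility report with all intermediates. With `censor_at_first_code`
#' (the default), incident cases stop contributing person-time at their
#' index date, and patients whose first disease code predates their
#' observation period (prevalent cases) contribute their full follow-up;
#' switching it off leaves all follow-up uncensored. The settings used
#' are reported in `log`.
#'
#' @param config A [sim_config()]; ignored when `tables` is given.
#' @param tables Optional list with `practices`, `patients`, `events`
#'   (e.g. [read_cohort()]); bypasses simulation.
#' @param collection Code lists; default the bundled synthetic lists
#'   (with history codes stripped from time-limited cautions).
#' @param survey Survey-response tibble; default the bundled synthetic
#'   survey.
#' @param population National population tibble (`band`, `population`);
#'   default the bundled example table.
#' @param study_start,study_end,linkage_date Observation-window dates.
#' @param years Projection window length in years.
#' @param projection_total Override for the pool total to partition
#'   (default: the extrapolated point total).
#' @param censor_at_first_code Censor incident cases' person-time at
#'   their index date (default `TRUE`).
#' @param icd10_prefix Match ICD-10 on 3-character prefixes.
#' @param out_dir Optional directory; when given, writes cases,
#'   person-time, caution summary, hits, and the report (CSV/JSON).
#' @return List of class `trialpool_run`: `report`
#'   (`feasibility_report`), plus `cohort`, `periods`, `person_time`,
#'   `cases`, `rates`, `projection`, `hits`, `caution_table`,
#'   `statuses`, `condition_statuses`, `dementia`, and `log`.
#' @export
run_pipeline <- function(config = sim_config(),
                         tables = NULL,
                         collection = strip_history_codes(
                           read_codelists(trialpool_example("codelists"))),
                         survey = read_survey(trialpool_example("survey")),
                         population = read_population(trialpool_example("population")),
                         study_start = as.Date("2015-01-01"),
                         study_end = as.Date("2017-12-31"),
                         linkage_date = as.Date("2018-03-31"),
                         years = 3,
                         projection_total = NULL,
                         censor_at_first_code = TRUE,
                         icd10_prefix = FALSE,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "': ", conditionMessage(e)))
    })
  }
  if (is.null(tables)) {
    cohort <- stage("simulate", generate_cohort(config, collection = collection))
    tables <- cohort[c("practices", "patients", "events")]
  } else {
    cohort <- NULL
  }

  periods <- stage("cohort", build_observation_periods(
    tables$patients, tables$practices, study_start, study_end, linkage_date))
  disease_spec <- codelist_spec(collection, role = "disease")
  cases <- stage("cohort", identify_incident_cases(
    tables$events, disease_spec, periods, tables$patients))
  if (nrow(cases) == 0) abort("pipeline stage 'report': no incident cases")

  pt_periods <- periods
  if (censor_at_first_code) {
    pt_periods <- periods |>
      left_join(cases |> select("patient_id", "index_date"), by = "patient_id") |>
      mutate(end = dplyr::coalesce(pmin(.data$end, .data$index_date), .data$end)) |>
      select("patient_id", "start", "end") |>
      filter(.data$start < .data$end)
  }
  person_time <- stage("incidence", person_time_by_band(pt_periods, tables$patients))
  rates <- stage("incidence", estimate_rates(cases, person_time))
  projection <- stage("incidence", extrapolate_cases(rates, population, years))
  pool_total <- projection_total %||% projection$total

  hits <- stage("eligibility", caution_profile(
    cases, tables$events, collection, tables$patients, tables$practices,
    icd10_prefix = icd10_prefix))
  caution_table <- caution_summary(hits, cases, collection)
  condition_statuses <- stage("consensus", classify_conditions(survey))
  statuses <- stage("consensus", classify_patients(cases, hits, condition_statuses))
  dem <- stage("eligibility", dementia_flags(
    cases, tables$events, codelist_spec(collection, role = "dementia"),
    tables$patients, tables$practices, icd10_prefix = icd10_prefix))
  report <- stage("report", build_report(cases, statuses, dem, pool_total))

  log <- c(
    paste0("censor_at_first_code=", censor_at_first_code),
    paste0("icd10_prefix=", icd10_prefix),
    paste0("projection_total=", format(pool_total)),
    paste0("study_window=", study_start, "..", study_end,
           " linkage=", linkage_date),
    paste0("incident_cases=", nrow(cases))
  )
  run <- structure(
    list(report = report, cohort = cohort, periods = periods,
         person_time = person_time, cases = cases, rates = rates,
         projection = projection, hits = hits, caution_table = caution_table,
         statuses = statuses, condition_statuses = condition_statuses,
         dementia = dem, log = log),
    class = "trialpool_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.trialpool_run <- function(x, ...) {
  cat("<trialpool_run>\n")
  for (l in x$log) cat("  ", l, "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' @param run A `trialpool_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "trialpool_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$cases, file.path(dir, "cases.csv"))
  readr::write_csv(run$person_time, file.path(dir, "person_time.csv"))
  readr::write_csv(tidy.incidence_estimates(run$rates),
                   file.path(dir, "incidence.csv"))
  readr::write_csv(run$hits, file.path(dir, "caution_hits.csv"))
  readr::write_csv(run$caution_table, file.path(dir, "caution_summary.csv"))
  readr::write_csv(run$report$by_status, file.path(dir, "report_by_status.csv"))
  write_report_json(run$report, file.path(dir, "report.json"))
  writeLines(run$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read a national population table
#'
#' @param path CSV with columns `band` (matching [age_band_levels()])
#'   and `population`.
#' @return Tibble `band`, `population`.
#' @export
read_population <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    band = readr::col_character(),
    population = readr::col_double()
  ))
}
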