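# Synthetic linked-EHR generator: practices, patients, and dual-source
# coded events with plantable age-specific disease incidence, comorbidity
# prevalence, and dementia. Every planted parameter is returned as ground
# truth so downstream stages can be tested against it.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [generate_cohort()].
#' Defaults emulate an English primary-care cohort observed 2015-2017
#' with an age profile weighted like the adult population, a steeply
#' age-rising planted incidence of the index disease (rare overall,
#' concentrated in the very old), age-band dementia prevalence, and
#' per-condition lifetime comorbidity prevalences of the same order as
#' those seen among elderly incident cases.
#'
#' @param n_practices Number of practices.
#' @param patients_per_practice Patients registered per practice.
#' @param study_start,study_end Study window dates.
#' @param birth_year_distribution Named probability vector over
#'   [age_band_levels()]: age-band shares at the study midpoint. Must sum
#'   to 1 (tolerance 1e-9).
#' @param annual_registration_turnover Per patient-year probability of
#'   joining/leaving a practice; controls registration tenure
#'   (exponential, mean `1/turnover` years) and transfer-out times.
#' @param planted_incidence Named rate vector over [age_band_levels()]:
#'   first-diagnosis incidence per 100,000 person-years planted within
#'   each patient's registered time.
#' @param caution_profiles Tibble `condition`, `prevalence`: lifetime
#'   probability a patient ever carries each comorbidity; onset is
#'   uniform over the patient's adult registered history. `NULL` plants
#'   the default profiles for the bundled condition list; a zero-row
#'   tibble plants none.
#' @param dementia_prevalence_by_band Named probability vector over
#'   [age_band_levels()]: dementia prevalence by age band at the end of
#'   the patient's record.
#' @param dual_recording_probability Length-3 probability vector
#'   `c(primary, hospital, both)`: where an incident diagnosis is
#'   recorded. Must sum to 1.
#' @param hospital_offset_days When recorded in both settings, the
#'   hospital record is dated this many days after the primary-care
#'   record (default 0: exercises the same-day source tie-break).
#' @param acceptable_probability Probability a patient record passes the
#'   research-quality check.
#' @param mortality_rate_coef,mortality_rate_base Gompertz-style annual
#'   death hazard `base * exp(coef * age)`, capped at 0.5.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   the cohort exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_practices = 10,
                       patients_per_practice = 500,
                       study_start = as.Date("2015-01-01"),
                       study_end = as.Date("2017-12-31"),
                       birth_year_distribution = default_age_distribution(),
                       annual_registration_turnover = 0.08,
                       planted_incidence = default_planted_incidence(),
                       caution_profiles = NULL,
                       dementia_prevalence_by_band = default_dementia_prevalence(),
                       dual_recording_probability = c(primary = 0.6, hospital = 0.2, both = 0.2),
                       hospital_offset_days = 0,
                       acceptable_probability = 0.97,
                       mortality_rate_coef = 0.085,
                       mortality_rate_base = 5e-5,
                       seed = 1L) {
  if (is.null(caution_profiles)) caution_profiles <- default_caution_profiles()
  cfg <- list(
    n_practices = n_practices,
    patients_per_practice = patients_per_practice,
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    birth_year_distribution = birth_year_distribution,
    annual_registration_turnover = annual_registration_turnover,
    planted_incidence = planted_incidence,
    caution_profiles = as_tibble(caution_profiles),
    dementia_prevalence_by_band = dementia_prevalence_by_band,
    dual_recording_probability = dual_recording_probability,
    hospital_offset_days = hospital_offset_days,
    acceptable_probability = acceptable_probability,
    mortality_rate_coef = mortality_rate_coef,
    mortality_rate_base = mortality_rate_base,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      abort(paste0("sim_config: ", field, " must lie in [0, 1]"))
    }
  }
  chk_bands <- function(x, field) {
    if (!setequal(names(x), age_band_levels())) {
      abort(paste0("sim_config: ", field, " must be named by all age bands"))
    }
  }
  if (cfg$n_practices < 1) abort("sim_config: n_practices must be >= 1")
  if (cfg$patients_per_practice < 1) {
    abort("sim_config: patients_per_practice must be >= 1")
  }
  if (cfg$study_start >= cfg$study_end) {
    abort("sim_config: study_start must precede study_end")
  }
  chk_bands(cfg$birth_year_distribution, "birth_year_distribution")
  chk_prob(cfg$birth_year_distribution, "birth_year_distribution")
  if (abs(sum(cfg$birth_year_distribution) - 1) > 1e-9) {
    abort("sim_config: birth_year_distribution must sum to 1")
  }
  chk_bands(cfg$planted_incidence, "planted_incidence")
  if (any(cfg$planted_incidence < 0)) {
    abort("sim_config: planted_incidence rates must be >= 0")
  }
  chk_bands(cfg$dementia_prevalence_by_band, "dementia_prevalence_by_band")
  chk_prob(cfg$dementia_prevalence_by_band, "dementia_prevalence_by_band")
  chk_prob(cfg$annual_registration_turnover, "annual_registration_turnover")
  if (length(cfg$dual_recording_probability) != 3 ||
      abs(sum(cfg$dual_recording_probability) - 1) > 1e-9) {
    abort("sim_config: dual_recording_probability must be 3 probabilities summing to 1")
  }
  chk_prob(cfg$dual_recording_probability, "dual_recording_probability")
  chk_prob(cfg$acceptable_probability, "acceptable_probability")
  if (nrow(cfg$caution_profiles) > 0) {
    if (!all(c("condition", "prevalence") %in% names(cfg$caution_profiles))) {
      abort("sim_config: caution_profiles needs columns condition, prevalence")
    }
    chk_prob(cfg$caution_profiles$prevalence, "caution_profiles$prevalence")
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_age_distribution <- function() {
  w <- c(30, 82, 90, 88, 80, 80, 88, 86, 78, 68, 64, 55, 40, 32, 22, 12, 5)
  setNames(w / sum(w), age_band_levels())
}

#' @rdname sim_config
#' @export
default_planted_incidence <- function() {
  setNames(c(0.2, 0.2, 0.3, 0.4, 0.5, 0.8, 1.2, 2, 3, 5, 8, 14, 24, 40,
             60, 80, 100), age_band_levels())
}

#' @rdname sim_config
#' @export
default_dementia_prevalence <- function() {
  setNames(c(rep(0, 10), 0.02, 0.04, 0.08, 0.14, 0.22, 0.30, 0.35),
           age_band_levels())
}

#' @rdname sim_config
#' @export
default_caution_profiles <- function() {
  tribble(
    ~condition,                        ~prevalence,
    "Diabetes mellitus",               0.20,
    "Diverticulitis",                  0.03,
    "Epilepsy",                        0.05,
    "Glaucoma",                        0.06,
    "Heart failure",                   0.14,
    "Hypertension",                    0.55,
    "Hypothyroidism",                  0.11,
    "Intestinal anastomosis",          0.01,
    "Malignancy (excluding BCC)",      0.12,
    "Myasthenia gravis",               0.005,
    "Myocardial infarction",           0.05,
    "Myopathy",                        0.005,
    "Ocular herpes simplex",           0.005,
    "Osteoporosis",                    0.13,
    "Peptic ulcer",                    0.03,
    "Septicaemia/sepsis",              0.03,
    "Severe mental illness",           0.02,
    "Systemic sclerosis",              0.002,
    "Venous thromboembolic disorders", 0.07,
    "Tuberculosis",                    0.01,
    "Ulcerative colitis",              0.01,
    "Varicella zoster vaccine",        0.04
  )
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path A `.yml`/`.yaml` or `.json` file whose keys are
#'   [sim_config()] arguments (dates as ISO-8601 strings,
#'   `caution_profiles` as a list of condition/prevalence records).
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("study_start", "study_end")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.Date(raw[[f]])
  }
  for (f in c("birth_year_distribution", "planted_incidence",
              "dementia_prevalence_by_band", "dual_recording_probability")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$caution_profiles)) {
    raw$caution_profiles <- as_tibble(raw$caution_profiles)
  }
  do.call(sim_config, raw)
}

#' Generate a synthetic linked-EHR cohort
#'
#' Produces practice, patient, and coded-event tables satisfying the
#' package's schema. Index-disease onsets arrive as an age-inhomogeneous
#' Poisson process over each patient's registered adult time, simulated
#' by thinning a homogeneous process at the maximum band rate (exact for
#' piecewise-constant rates); the first arrival is the planted onset and
#' is recorded in primary care, hospital, or both per the dual-recording
#' probabilities. Comorbidities and dementia are planted per profile with
#' onsets uniform over the registered adult record. The same config (and
#' seed) reproduces the tables exactly.
#'
#' @param config A [sim_config()].
#' @param collection A `codelist_collection` supplying the codes to emit;
#'   defaults to the bundled synthetic lists.
#' @return List of class `ehr_cohort`: tibbles `practices`, `patients`,
#'   `events`, plus `truth` (list of `disease` and `conditions` tibbles
#'   of planted onsets) and `config`.
#' @export
generate_cohort <- function(config = sim_config(),
                            collection = read_codelists(trialpool_example("codelists"))) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  practices <- generate_practices(config)
  patients <- generate_patients(config, practices)
  disease <- plant_disease_events(
    patients, practices,
    planted_incidence = config$planted_incidence,
    disease_spec = codelist_spec(collection, role = "disease"),
    dual_recording_probability = config$dual_recording_probability,
    hospital_offset_days = config$hospital_offset_days
  )
  cond <- plant_condition_events(patients, practices, config, collection)
  events <- bind_rows(disease$events, cond$events) |>
    arrange(.data$patient_id, .data$event_date, .data$source_table, .data$code)
  structure(
    list(practices = practices, patients = patients, events = events,
         truth = list(disease = disease$truth, conditions = cond$truth),
         config = config),
    class = "ehr_cohort"
  )
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort>: ", nrow(x$patients), " patients in ",
      nrow(x$practices), " practices; ", nrow(x$events), " events (",
      nrow(x$truth$disease), " planted index-disease onsets)\n", sep = "")
  invisible(x)
}

generate_practices <- function(config) {
  n <- config$n_practices
  tibble(
    practice_id = sprintf("pr%03d", seq_len(n)),
    up_to_standard_date = config$study_start -
      round(runif(n, 5 * 365.25, 20 * 365.25)),
    last_collection_date = config$study_end + round(runif(n, 90, 540)),
    hes_linked = TRUE
  )
}

generate_patients <- function(config, practices) {
  n <- config$n_practices * config$patients_per_practice
  ref <- as.Date(paste0(format(config$study_start, "%Y"), "-07-01")) +
    round(days_between(config$study_start, config$study_end) / 2)
  ref_year <- as.integer(format(config$study_start, "%Y")) + 1L

  band_idx <- sample.int(length(age_band_levels()), n, replace = TRUE,
                         prob = config$birth_year_distribution)
  lo <- band_lower_edges()[band_idx]
  hi <- c(band_lower_edges()[-1] - 1L, 99L)[band_idx]
  age_ref <- lo + floor(runif(n) * (hi - lo + 1))
  birth_year <- ref_year - age_ref  # completed age at mid-study 1 July

  pid <- sprintf("pt%07d", seq_len(n))
  practice_id <- rep(practices$practice_id,
                     length.out = n)[order(runif(n))]
  adult <- imputed_birthdate(birth_year + 18L)
  tenure_days <- rexp(n, rate = config$annual_registration_turnover) * 365.25
  registration <- pmax(config$study_end - round(tenure_days), adult)

  pr <- practices[match(practice_id, practices$practice_id), ]
  transfer_days <- rexp(n, rate = config$annual_registration_turnover) * 365.25
  transfer <- registration + round(transfer_days)
  transfer[transfer > pr$last_collection_date] <- NA

  age_reg <- age_at(birth_year, registration)
  death_rate <- pmin(config$mortality_rate_base *
                       exp(config$mortality_rate_coef * age_reg), 0.5)
  death <- registration + round(rexp(n, rate = death_rate) * 365.25)
  death[death > config$study_end + 730] <- NA
  transfer[!is.na(death) & !is.na(transfer) & transfer > death] <- NA

  tibble(
    patient_id = pid,
    practice_id = practice_id,
    birth_year = as.integer(birth_year),
    sex = ifelse(runif(n) < 0.51, "F", "M"),
    current_registration_date = registration,
    transfer_out_date = transfer,
    death_date = death,
    acceptable = runif(n) < config$acceptable_probability
  )
}

# registered adult interval during which events can be recorded
recorded_interval <- function(patients, practices) {
  pr <- practices[match(patients$practice_id, practices$practice_id), ]
  start <- pmax(patients$current_registration_date,
                imputed_birthdate(patients$birth_year + 18L))
  end <- pmin(
    pr$last_collection_date,
    dplyr::coalesce(patients$death_date, pr$last_collection_date),
    dplyr::coalesce(patients$transfer_out_date, pr$last_collection_date)
  )
  tibble(patient_id = patients$patient_id, start = start, end = end,
         birth_year = patients$birth_year)
}

#' Plant index-disease onsets and their recordings
#'
#' The event-planting stage of [generate_cohort()], exported so disease
#' arrivals can be re-simulated over a fixed patient panel (e.g. for
#' replicate studies of estimator coverage). Arrivals follow an
#' age-inhomogeneous Poisson process at the planted band rates over each
#' patient's registered adult time, via thinning at the maximum band
#' rate. Uses the current RNG state unless `seed` is given.
#'
#' @param patients,practices Cohort tables.
#' @param planted_incidence Named band rate vector per 100,000
#'   person-years.
#' @param disease_spec Disease specification ([codelist_spec()]).
#' @param dual_recording_probability Length-3 `c(primary, hospital, both)`.
#' @param hospital_offset_days Hospital-record date offset when recorded
#'   in both settings.
#' @param seed Optional integer seed.
#' @return List: `events` tibble (possibly zero rows) and `truth` tibble
#'   (`patient_id`, `onset_date`, `recorded_in`).
#' @export
plant_disease_events <- function(patients, practices, planted_incidence,
                                 disease_spec,
                                 dual_recording_probability = c(0.6, 0.2, 0.2),
                                 hospital_offset_days = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  iv <- recorded_interval(patients, practices)
  iv <- iv[iv$start < iv$end, ]
  rate_max <- max(planted_incidence) / 1e5
  empty <- list(events = empty_events(), truth = tibble(
    patient_id = character(), onset_date = as.Date(character()),
    recorded_in = character()
  ))
  if (rate_max == 0 || nrow(iv) == 0) return(empty)

  py <- days_between(iv$start, iv$end) / 365.25
  n_cand <- rpois(nrow(iv), rate_max * py)
  idx <- rep.int(seq_len(nrow(iv)), n_cand)
  if (length(idx) == 0) return(empty)
  t_cand <- iv$start[idx] +
    floor(runif(length(idx)) * days_between(iv$start[idx], iv$end[idx]))
  band_cand <- as.character(age_band(age_at(iv$birth_year[idx], t_cand)))
  accept <- runif(length(idx)) <
    planted_incidence[band_cand] / 1e5 / rate_max
  if (!any(accept)) return(empty)
  keep <- tibble(patient_id = iv$patient_id[idx][accept],
                 onset_date = t_cand[accept]) |>
    group_by(.data$patient_id) |>
    summarise(onset_date = min(.data$onset_date), .groups = "drop")
  if (nrow(keep) == 0) return(empty)

  dest <- c("primary", "hospital", "both")[
    max.col(stats::rmultinom(nrow(keep), 1, dual_recording_probability) |> t())
  ]
  read_codes <- disease_spec$codes |> filter(.data$system %in% c("READ", "PRODUCT"))
  icd_codes <- disease_spec$codes |> filter(.data$system == "ICD10")
  if (nrow(read_codes) == 0) read_codes <- disease_spec$codes
  if (nrow(icd_codes) == 0) icd_codes <- disease_spec$codes

  prim <- dest %in% c("primary", "both")
  hosp <- dest %in% c("hospital", "both")
  prim_rows <- tibble(
    patient_id = keep$patient_id[prim],
    event_date = keep$onset_date[prim],
    code = read_codes$code[sample.int(nrow(read_codes), sum(prim), replace = TRUE)],
    coding_system = "READ",
    source_table = "clinical"
  )
  hosp_date <- keep$onset_date[hosp] +
    ifelse(dest[hosp] == "both", hospital_offset_days, 0)
  hosp_rows <- tibble(
    patient_id = keep$patient_id[hosp],
    event_date = hosp_date,
    code = icd_codes$code[sample.int(nrow(icd_codes), sum(hosp), replace = TRUE)],
    coding_system = "ICD10",
    source_table = "hes_diagnosis"
  )
  list(
    events = bind_rows(prim_rows, hosp_rows),
    truth = keep |> mutate(recorded_in = dest)
  )
}

# comorbidity and dementia planting: Bernoulli carriage per condition,
# onset uniform over the registered adult record; independent across
# conditions (no correlation structure is modelled)
plant_condition_events <- function(patients, practices, config, collection) {
  iv <- recorded_interval(patients, practices)
  iv <- iv[iv$start < iv$end, ]
  truth0 <- tibble(patient_id = character(), condition = character(),
                   onset_date = as.Date(character()))
  out_events <- list()
  out_truth <- list()

  profiles <- config$caution_profiles
  if (nrow(iv) > 0 && nrow(profiles) > 0) {
    known <- caution_names(collection)
    unknown <- setdiff(profiles$condition, known)
    if (length(unknown) > 0) {
      abort(paste0("caution_profiles: no code list for condition(s): ",
                   paste(unknown, collapse = ", ")))
    }
    for (i in seq_len(nrow(profiles))) {
      cond <- profiles$condition[i]
      carrier <- runif(nrow(iv)) < profiles$prevalence[i]
      if (!any(carrier)) next
      onset <- iv$start[carrier] + floor(runif(sum(carrier)) *
                                           days_between(iv$start[carrier], iv$end[carrier]))
      spec <- codelist_spec(collection, cond)
      out <- emit_condition_rows(iv$patient_id[carrier], onset, spec)
      out_events[[length(out_events) + 1]] <- out
      out_truth[[length(out_truth) + 1]] <-
        tibble(patient_id = iv$patient_id[carrier], condition = cond,
               onset_date = onset)
    }
  }

  dem <- config$dementia_prevalence_by_band
  if (nrow(iv) > 0 && any(dem > 0) &&
      any(collection$conditions$role == "dementia")) {
    band_end <- as.character(age_band(age_at(iv$birth_year, iv$end - 1)))
    carrier <- runif(nrow(iv)) < dem[band_end]
    if (any(carrier)) {
      lo <- pmax(iv$start[carrier], iv$end[carrier] - round(10 * 365.25))
      onset <- lo + floor(runif(sum(carrier)) *
                            pmax(days_between(lo, iv$end[carrier]), 1))
      spec <- codelist_spec(collection, role = "dementia")
      out_events[[length(out_events) + 1]] <-
        emit_condition_rows(iv$patient_id[carrier], onset, spec)
      out_truth[[length(out_truth) + 1]] <-
        tibble(patient_id = iv$patient_id[carrier],
               condition = spec$condition, onset_date = onset)
    }
  }

  list(
    events = if (length(out_events)) list_rbind(out_events) else empty_events(),
    truth = if (length(out_truth)) list_rbind(out_truth) else truth0
  )
}

# one coded row per onset; code sampled among the condition's non-history
# codes and routed to a source table by its coding system
emit_condition_rows <- function(patient_id, onset, spec) {
  codes <- spec$codes |> filter(!.data$is_history)
  if (nrow(codes) == 0) codes <- spec$codes
  pick <- sample.int(nrow(codes), length(patient_id), replace = TRUE)
  system <- codes$system[pick]
  source_table <- dplyr::case_match(
    system,
    "READ" ~ "clinical",
    "PRODUCT" ~ "therapy",
    "ICD10" ~ "hes_diagnosis",
    "OPCS" ~ "hes_procedure"
  )
  # spread a share of Read-coded rows across the other primary-care tables
  is_read <- system == "READ"
  alt <- sample(c("clinical", "clinical", "referral", "test"),
                sum(is_read), replace = TRUE)
  source_table[is_read] <- alt
  tibble(patient_id = patient_id, event_date = onset, code = codes$code[pick],
         coding_system = system, source_table = source_table)
}

empty_events <- function() {
  tibble(patient_id = character(), event_date = as.Date(character()),
         code = character(), coding_system = character(),
         source_table = character())
}

#' Write a cohort to CSV with its configuration mirrored alongside
#'
#' Writes `practices.csv`, `patients.csv`, `events.csv` (ISO-8601 dates)
#' and `config.json` (provenance mirror of the generating configuration)
#' into `dir`.
#'
#' @param cohort An `ehr_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$practices, file.path(dir, "practices.csv"), na = "")
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), na = "")
  readr::write_csv(cohort$events, file.path(dir, "events.csv"), na = "")
  cfg <- unclass(cohort$config)
  cfg$study_start <- format(cfg$study_start)
  cfg$study_end <- format(cfg$study_end)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Directory containing the three CSVs.
#' @return List with tibbles `practices`, `patients`, `events`.
#' @export
read_cohort <- function(dir) {
  list(
    practices = readr::read_csv(file.path(dir, "practices.csv"),
      col_types = readr::cols(
        practice_id = readr::col_character(),
        up_to_standard_date = readr::col_date(),
        last_collection_date = readr::col_date(),
        hes_linked = readr::col_logical()
      )),
    patients = readr::read_csv(file.path(dir, "patients.csv"),
      col_types = readr::cols(
        patient_id = readr::col_character(),
        practice_id = readr::col_character(),
        birth_year = readr::col_integer(),
        sex = readr::col_character(),
        current_registration_date = readr::col_date(),
        transfer_out_date = readr::col_date(),
        death_date = readr::col_date(),
        acceptable = readr::col_logical()
      )),
    events = readr::read_csv(file.path(dir, "events.csv"),
      col_types = readr::cols(
        patient_id = readr::col_character(),
        event_date = readr::col_date(),
        code = readr::col_character(),
        coding_system = readr::col_character(),
        source_table = readr::col_character()
      ))
  )
}
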