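small_config <- function(...) {
  sim_config(n_practices = 2, patients_per_practice = 150, seed = 9L, ...)
}

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_practices = 0), "n_practices")
  bad_dist <- default_age_distribution(); bad_dist[1] <- bad_dist[1] + 1e-6
  expect_error(sim_config(birth_year_distribution = bad_dist), "sum to 1")
  bad_inc <- default_planted_incidence(); bad_inc[3] <- -1
  expect_error(sim_config(planted_incidence = bad_inc), "planted_incidence")
  expect_error(sim_config(dual_recording_probability = c(0.5, 0.5, 0.5)),
               "dual_recording_probability")
  expect_error(sim_config(annual_registration_turnover = 1.2),
               "annual_registration_turnover")
  expect_error(sim_config(study_start = "2018-01-01", study_end = "2015-01-01"),
               "study_start")
  expect_error(sim_config(caution_profiles = tibble::tibble(
    condition = "X", prevalence = 2)), "prevalence")
})

test_that("the same configuration reproduces the cohort byte for byte", {
  c1 <- generate_cohort(small_config())
  c2 <- generate_cohort(small_config())
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$practices, c2$practices)
  expect_identical(c1$events, c2$events)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("practices.csv", "patients.csv", "events.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed moves at least the event table
  c3 <- generate_cohort(sim_config(n_practices = 2, patients_per_practice = 150,
                                   seed = 10L))
  expect_false(identical(c1$events, c3$events))
})

test_that("zero planted incidence yields no disease codes", {
  cohort <- generate_cohort(small_config(planted_incidence = zero_bands()))
  disease_codes <- codelist_spec(fixture_collection(), role = "disease")$codes$code
  expect_false(any(cohort$events$code %in% disease_codes))
  expect_equal(nrow(cohort$truth$disease), 0)
})

test_that("generated tables satisfy the schema invariants", {
  cohort <- generate_cohort(small_config(planted_incidence = flat_rates(500)))
  pa <- cohort$patients; pr <- cohort$practices; ev <- cohort$events
  expect_true(all(pr$up_to_standard_date <= pr$last_collection_date))
  both <- !is.na(pa$transfer_out_date)
  expect_true(all(pa$current_registration_date[both] < pa$transfer_out_date[both]))
  dd <- !is.na(pa$death_date)
  expect_true(all(pa$death_date[dd] >= pa$current_registration_date[dd]))
  # coding system consistent with source table
  expect_true(all(ev$coding_system[ev$source_table == "hes_diagnosis"] == "ICD10"))
  expect_true(all(ev$coding_system[ev$source_table == "hes_procedure"] == "OPCS"))
  expect_true(all(ev$coding_system[ev$source_table %in%
    c("clinical", "referral", "test")] == "READ"))
  # no event before the 18th birthday or after death
  ev2 <- dplyr::inner_join(ev, pa, by = "patient_id")
  expect_true(all(ev2$event_date >= imputed_birthdate(ev2$birth_year + 18L)))
  dd2 <- !is.na(ev2$death_date)
  expect_true(all(ev2$event_date[dd2] <= ev2$death_date[dd2]))
})

test_that("cohorts round-trip through CSV", {
  cohort <- generate_cohort(small_config())
  dir <- tempfile()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients, cohort$patients)
  expect_equal(back$practices, cohort$practices)
  expect_equal(back$events, cohort$events)
  expect_true(file.exists(file.path(dir, "config.json")))
})

test_that("planted band rates are recovered within sampling error", {
  # one mid-size cohort; every band with >= 50 expected events must
  # estimate within 3/sqrt(expected) relative error
  rates <- flat_rates(300)
  cohort <- generate_cohort(sim_config(
    n_practices = 10, patients_per_practice = 20000,
    planted_incidence = rates, annual_registration_turnover = 0.06,
    caution_profiles = no_cautions(),
    dementia_prevalence_by_band = zero_bands(), seed = 21L))
  periods <- build_observation_periods(cohort$patients, cohort$practices)
  pt <- person_time_by_band(periods, cohort$patients)
  cases <- identify_incident_cases(
    cohort$events, codelist_spec(fixture_collection(), role = "disease"),
    periods, cohort$patients)
  est <- estimate_rates(cases, pt)
  bands <- est[est$band != "CRUDE" & est$person_years > 0, ]
  expected <- rates[bands$band] / 1e5 * bands$person_years
  check <- expected >= 50
  expect_gt(sum(check), 3)  # the test must actually exercise several bands
  rel_err <- abs(bands$rate - rates[bands$band]) / rates[bands$band]
  expect_true(all(rel_err[check] < 3 / sqrt(expected[check])))
})

test_that("identified index dates equal planted first-recording dates", {
  cohort <- generate_cohort(small_config(planted_incidence = flat_rates(3000)))
  periods <- build_observation_periods(cohort$patients, cohort$practices)
  cases <- identify_incident_cases(
    cohort$events, codelist_spec(fixture_collection(), role = "disease"),
    periods, cohort$patients)
  expect_gt(nrow(cases), 5)
  truth <- cohort$truth$disease
  m <- dplyr::inner_join(cases, truth, by = "patient_id")
  expect_equal(nrow(m), nrow(cases))
  # hospital offset is zero by default, so recording date == onset date
  expect_equal(m$index_date, m$onset_date)
})

test_that("configuration files load from YAML and JSON", {
  yml <- tempfile(fileext = ".yml")
  writeLines(c(
    "n_practices: 3",
    "patients_per_practice: 10",
    "study_start: 2015-01-01",
    "study_end: 2017-12-31",
    "seed: 4"
  ), yml)
  cfg <- read_sim_config(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_practices, 3)
  expect_equal(cfg$seed, 4L)
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_practices = 2, patients_per_practice = 5,
                            seed = 8), js, auto_unbox = TRUE)
  cfg2 <- read_sim_config(js)
  expect_equal(cfg2$n_practices, 2)
})
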