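practices1 <- mk_practice(up_to_standard_date = "2005-01-01")

test_that("observation period start is the latest of its four terms", {
  # study window dominates both bounds
  p <- build_observation_periods(mk_patient(registration = "2010-05-01"),
                                 practices1)
  expect_equal(p$start, as.Date("2015-01-01"))
  expect_equal(p$end, as.Date("2017-12-31"))
  # registration + 12 months is the latest term
  p <- build_observation_periods(mk_patient(registration = "2014-09-15"),
                                 practices1)
  expect_equal(p$start, as.Date("2015-09-15"))
  # 18th birthday term (born 1998 -> adult 2016-07-01)
  p <- build_observation_periods(mk_patient(birth_year = 1998L,
                                            registration = "2000-01-01"),
                                 practices1)
  expect_equal(p$start, as.Date("2016-07-01"))
  # up-to-standard date term
  p <- build_observation_periods(mk_patient(registration = "2000-01-01"),
                                 mk_practice(up_to_standard_date = "2016-03-01"))
  expect_equal(p$start, as.Date("2016-03-01"))
})

test_that("observation period end is the earliest of its terms", {
  p <- build_observation_periods(mk_patient(death = "2016-02-01"), practices1)
  expect_equal(p$end, as.Date("2016-02-01"))
  p <- build_observation_periods(mk_patient(transfer = "2015-08-10"), practices1)
  expect_equal(p$end, as.Date("2015-08-10"))
  p <- build_observation_periods(mk_patient(), practices1,
                                 linkage_date = as.Date("2017-03-31"))
  expect_equal(p$end, as.Date("2017-03-31"))
})

test_that("empty or invalid periods yield no row", {
  # registration + 12 months after study end
  expect_equal(nrow(build_observation_periods(
    mk_patient(registration = "2017-06-01"), practices1)), 0)
  # non-acceptable patients are dropped
  expect_equal(nrow(build_observation_periods(
    mk_patient(acceptable = FALSE), practices1)), 0)
})

test_that("person-time splits exactly at band-boundary birthdays", {
  # born 1936: 80th birthday 2016-07-01; observed 2015-07-01..2017-07-01
  pat <- mk_patient(birth_year = 1936L)
  periods <- tibble::tibble(patient_id = "pt1",
                            start = as.Date("2015-07-01"),
                            end = as.Date("2017-07-01"))
  pt <- person_time_by_band(periods, pat)
  expect_equal(pt$person_years[pt$band == "75-79"], 366 / 365.25)
  expect_equal(pt$person_years[pt$band == "80-84"], 365 / 365.25)
  expect_equal(sum(pt$person_years), 731 / 365.25)
})

test_that("empty period list gives an all-zero table", {
  pt <- person_time_by_band(tibble::tibble(patient_id = character(),
                                           start = as.Date(character()),
                                           end = as.Date(character())),
                            mk_patient())
  expect_equal(sum(pt$person_years), 0)
  expect_equal(nrow(pt), length(age_band_levels()))
})

test_that("band person-time agrees with day-by-day accumulation and conserves totals", {
  set.seed(101)
  for (rep in 1:3) {
    n <- 12
    patients <- mk_patient(patient_id = paste0("pt", 1:n),
                           birth_year = sample(1920:1995, n, replace = TRUE))
    start <- as.Date("2015-01-01") + sample(0:600, n, replace = TRUE)
    periods <- tibble::tibble(patient_id = patients$patient_id, start = start,
                              end = start + sample(30:900, n, replace = TRUE))
    got <- person_time_by_band(periods, patients)
    want <- oracle_person_time(periods, patients)
    expect_equal(got$person_years, want$person_years, tolerance = 1e-9)
    expect_equal(sum(got$person_years),
                 sum(as.numeric(periods$end - periods$start)) / 365.25,
                 tolerance = 1e-9)
  }
})

test_that("person_time_by_band rejects unknown patients", {
  periods <- tibble::tibble(patient_id = "ghost",
                            start = as.Date("2015-01-01"),
                            end = as.Date("2016-01-01"))
  expect_error(person_time_by_band(periods, mk_patient()), "unknown patient")
})

disease_spec <- function() codelist_spec(fixture_collection(), role = "disease")

test_that("incident cases respect the registration lag and the window", {
  periods <- build_observation_periods(mk_patient(), practices1)
  # first code inside window, long after registration -> incident
  ev <- mk_events("pt1", "2016-03-01", "M145.")
  cases <- identify_incident_cases(ev, disease_spec(), periods, mk_patient())
  expect_equal(cases$index_date, as.Date("2016-03-01"))
  expect_equal(cases$index_source, "primary_care")
  expect_equal(cases$age_at_index, 75L)
  # first code 6 months after registration -> not incident
  pat <- mk_patient(registration = "2014-09-15")
  per <- build_observation_periods(pat, practices1)
  ev <- mk_events("pt1", "2015-03-15", "M145.")
  expect_equal(nrow(identify_incident_cases(ev, disease_spec(), per, pat)), 0)
  # first-ever code before the window -> prevalent, never incident
  ev <- mk_events("pt1", c("2014-06-01", "2016-05-01"), "M145.")
  expect_equal(nrow(identify_incident_cases(ev, disease_spec(), periods,
                                            mk_patient())), 0)
})

test_that("the earliest code across sources sets the index; ties go to primary care", {
  periods <- build_observation_periods(mk_patient(), practices1)
  ev <- dplyr::bind_rows(
    mk_events("pt1", "2016-03-01", "L12.0", "ICD10", "hes_diagnosis"),
    mk_events("pt1", "2016-03-05", "M145.")
  )
  cases <- identify_incident_cases(ev, disease_spec(), periods, mk_patient())
  expect_equal(cases$index_date, as.Date("2016-03-01"))
  expect_equal(cases$index_source, "hospital")
  # same-day tie resolves to primary care
  ev <- dplyr::bind_rows(
    mk_events("pt1", "2016-03-01", "L12.0", "ICD10", "hes_diagnosis"),
    mk_events("pt1", "2016-03-01", "M145.")
  )
  cases <- identify_incident_cases(ev, disease_spec(), periods, mk_patient())
  expect_equal(cases$index_source, "primary_care")
})

test_that("incident count is monotone non-increasing in the lag length", {
  set.seed(77)
  cohort <- generate_cohort(sim_config(
    n_practices = 3, patients_per_practice = 800,
    planted_incidence = flat_rates(300),
    caution_profiles = no_cautions(),
    dementia_prevalence_by_band = zero_bands(), seed = 5L))
  periods <- build_observation_periods(cohort$patients, cohort$practices)
  counts <- vapply(c(0, 6, 12, 24, 48), function(lag) {
    nrow(identify_incident_cases(cohort$events, disease_spec(), periods,
                                 cohort$patients, lag_months = lag))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
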