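idx <- as.Date("2016-06-15")
reg <- as.Date("2011-03-01")
uts <- as.Date("2000-01-01")

test_that("time-limited windows are half-open at the index date", {
  spec <- mk_spec("Varicella zoster vaccine", "VZVAX1", "PRODUCT",
                  "MONTHS_BEFORE", 3L)
  # 2 months before: hit
  ev <- mk_events("pt1", "2016-04-15", "VZVAX1", "PRODUCT", "therapy")
  expect_equal(nrow(match_caution(ev, spec, idx, reg, uts)), 1)
  # 4 months before: outside the window
  ev <- mk_events("pt1", "2016-02-15", "VZVAX1", "PRODUCT", "therapy")
  expect_equal(nrow(match_caution(ev, spec, idx, reg, uts)), 0)
  # dated on the index date itself: never qualifies
  ev <- mk_events("pt1", "2016-06-15", "VZVAX1", "PRODUCT", "therapy")
  expect_equal(nrow(match_caution(ev, spec, idx, reg, uts)), 0)
  # exactly at the window's lower edge: qualifies (closed below)
  ev <- mk_events("pt1", "2016-03-15", "VZVAX1", "PRODUCT", "therapy")
  expect_equal(match_caution(ev, spec, idx, reg, uts)$earliest_date,
               as.Date("2016-03-15"))
})

test_that("time-limited hits require 12 months after registration", {
  spec <- mk_spec("Septicaemia/sepsis", "SE01.", window_kind = "MONTHS_BEFORE",
                  window_length = 3L)
  # 2 months before index but only 6 months after registration: no hit
  ev <- mk_events("pt1", "2016-04-15", "SE01.")
  expect_equal(nrow(match_caution(ev, spec, idx, as.Date("2015-10-15"), uts)), 0)
  # same code with an old registration: hit
  expect_equal(nrow(match_caution(ev, spec, idx, reg, uts)), 1)
})

test_that("any-time-before cautions look back to the up-to-standard date", {
  spec <- mk_spec("Osteoporosis", "OP01.")
  # 20 years before index: hit
  ev <- mk_events("pt1", "1996-06-15", "OP01.")
  expect_equal(nrow(match_caution(ev, spec, idx, reg, as.Date("1995-01-01"))), 1)
  # before the practice was up-to-standard: not usable history
  expect_equal(nrow(match_caution(ev, spec, idx, reg, as.Date("2000-01-01"))), 0)
  # the 12-month registration guard does not apply to ANY_BEFORE
  ev <- mk_events("pt1", "2016-05-01", "OP01.")
  expect_equal(nrow(match_caution(ev, spec, idx, as.Date("2016-01-01"), uts)), 1)
})

test_that("earliest qualifying date is reported", {
  spec <- mk_spec("Osteoporosis", "OP01.")
  ev <- mk_events("pt1", c("2010-01-01", "2005-05-05", "2016-06-20"), "OP01.")
  hit <- match_caution(ev, spec, idx, reg, uts)
  expect_equal(hit$earliest_date, as.Date("2005-05-05"))
})

test_that("window matching agrees with a brute-force row scan", {
  set.seed(202)
  codes <- c("AA1.", "BB2.", "Z99.1", "VZVAX1")
  systems <- c("READ", "READ", "ICD10", "PRODUCT")
  for (i in 1:60) {
    n_ev <- sample(0:8, 1)
    pick <- sample(4, n_ev, replace = TRUE)
    ev <- tibble::tibble(
      patient_id = "pt1",
      event_date = as.Date("2010-01-01") + sample(0:3000, max(n_ev, 1),
                                                  replace = TRUE)[seq_len(n_ev)],
      code = codes[pick],
      coding_system = systems[pick],
      source_table = "clinical"
    )
    wk <- sample(c("ANY_BEFORE", "MONTHS_BEFORE", "YEARS_BEFORE"), 1)
    spick <- sample(4, 2)
    spec <- mk_spec("X", codes[spick], systems[spick],
                    wk, if (wk == "ANY_BEFORE") NA_integer_ else sample(1:24, 1))
    index <- as.Date("2012-01-01") + sample(0:2000, 1)
    regd <- index - sample(100:4000, 1)
    utsd <- as.Date("2008-01-01") + sample(0:1500, 1)
    got <- match_caution(ev, spec, index, regd, utsd)
    want <- oracle_match_caution(ev, spec, index, regd, utsd)
    if (is.na(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$earliest_date, want)
    }
  }
})

test_that("shrinking a window never creates a new hit", {
  set.seed(303)
  for (i in 1:40) {
    ev <- mk_events("pt1", as.Date("2012-01-01") + sample(0:1800, 5), "AA1.")
    index <- as.Date("2016-06-01"); regd <- as.Date("2010-01-01")
    lens <- sort(sample(1:60, 4))
    hits <- vapply(lens, function(k) {
      nrow(match_caution(ev, mk_spec("X", "AA1.", window_kind = "MONTHS_BEFORE",
                                     window_length = k),
                         index, regd, uts)) > 0
    }, logical(1))
    # once a longer window misses, every shorter window must miss too
    expect_true(all(diff(as.integer(hits)) >= 0))
  }
})

test_that("caution_profile matches per-patient and is order-invariant", {
  cl <- fixture_collection()
  practices <- mk_practice()
  patients <- dplyr::bind_rows(
    mk_patient("pt1", registration = "2010-01-01"),
    mk_patient("pt2", registration = "2010-01-01"),
    mk_patient("pt3", registration = "2010-01-01")
  )
  cases <- tibble::tibble(patient_id = c("pt1", "pt2", "pt3"),
                          index_date = as.Date("2016-06-15"))
  events <- dplyr::bind_rows(
    mk_events("pt1", "2014-01-01", "OP01."),            # osteoporosis, any time
    mk_events("pt1", "2016-05-01", "VZVAX1", "PRODUCT", "therapy"),
    mk_events("pt2", "2016-01-01", "Z11.1", "ICD10", "hes_diagnosis"),
    mk_events("pt3", "2002-05-01", "OP01.")             # pt3: hit (any time)
  )
  hits <- caution_profile(cases, events, cl, patients, practices)
  sets <- split(hits$condition, hits$patient_id)
  expect_setequal(sets$pt1, c("Osteoporosis", "Varicella zoster vaccine"))
  expect_equal(sets$pt2, "Myocardial infarction")  # Z11.1 is the MI ICD-10 code
  expect_equal(sets$pt3, "Osteoporosis")
  shuffled <- events[sample(nrow(events)), ]
  expect_equal(caution_profile(cases, shuffled, cl, patients, practices), hits)
  # a patient whose only code falls after their index date has no rows
  cases0 <- tibble::tibble(patient_id = "pt2", index_date = as.Date("2015-06-15"))
  expect_equal(nrow(caution_profile(cases0, events[3, ], cl, patients, practices)), 0)
})

test_that("dementia is flagged only strictly before the index date", {
  cl <- fixture_collection()
  spec <- codelist_spec(cl, role = "dementia")
  practices <- mk_practice()
  patients <- dplyr::bind_rows(mk_patient("pt1"), mk_patient("pt2"),
                               mk_patient("pt3"))
  cases <- tibble::tibble(patient_id = c("pt1", "pt2", "pt3"),
                          index_date = as.Date("2016-06-15"))
  events <- dplyr::bind_rows(
    mk_events("pt1", "2016-06-14", "DE01."),  # 1 day before: flagged
    mk_events("pt2", "2016-06-15", "DE01.")   # on the index date: not flagged
  )
  flags <- dementia_flags(cases, events, spec, patients, practices)
  expect_equal(flags$dementia[match(c("pt1", "pt2", "pt3"), flags$patient_id)],
               c(TRUE, FALSE, FALSE))
})
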