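# In-code builders for tiny cohorts, plus independent brute-force oracles
# used to cross-check the vectorized implementations.

mk_practice <- function(practice_id = "pr001",
                        up_to_standard_date = as.Date("2000-01-01"),
                        last_collection_date = as.Date("2019-06-30")) {
  tibble::tibble(practice_id = practice_id,
                 up_to_standard_date = as.Date(up_to_standard_date),
                 last_collection_date = as.Date(last_collection_date),
                 hes_linked = TRUE)
}

mk_patient <- function(patient_id = "pt1", practice_id = "pr001",
                       birth_year = 1940L,
                       registration = as.Date("2010-05-01"),
                       transfer = NA, death = NA, acceptable = TRUE,
                       sex = "F") {
  tibble::tibble(patient_id = patient_id, practice_id = practice_id,
                 birth_year = as.integer(birth_year), sex = sex,
                 current_registration_date = as.Date(registration),
                 transfer_out_date = as.Date(transfer),
                 death_date = as.Date(death), acceptable = acceptable)
}

mk_events <- function(patient_id, event_date, code,
                      coding_system = "READ", source_table = "clinical") {
  tibble::tibble(patient_id = patient_id, event_date = as.Date(event_date),
                 code = code, coding_system = coding_system,
                 source_table = source_table)
}

mk_spec <- function(condition = "Test condition", codes = "C1",
                    system = "READ", window_kind = "ANY_BEFORE",
                    window_length = NA_integer_, status = "WITH_CAUTION") {
  list(condition = condition, window_kind = window_kind,
       window_length = window_length, status = status,
       codes = tibble::tibble(code = codes,
                              system = rep(system, length.out = length(codes)),
                              is_history = FALSE))
}

fixture_collection <- function() {
  read_codelists(trialpool_example("codelists"))
}

# independent calendar-month shift with day clamping (no lubridate):
# target (year, month) computed by hand, day clamped to the month length
oracle_shift_months <- function(date, n) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  tot <- (y * 12L + (m - 1L)) + as.integer(n)
  y2 <- tot %/% 12L
  m2 <- tot %% 12L + 1L
  last <- as.integer(format(
    seq(as.Date(sprintf("%04d-%02d-01", y2, m2)), by = "month", length.out = 2)[2] - 1,
    "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y2, m2, min(d, last)))
}

# day-by-day person-time accumulation: each day in [start, end) is
# attributed to the band of the patient's completed age that day
oracle_person_time <- function(periods, patients) {
  acc <- stats::setNames(rep(0, length(age_band_levels())), age_band_levels())
  for (i in seq_len(nrow(periods))) {
    by <- patients$birth_year[match(periods$patient_id[i], patients$patient_id)]
    days <- seq(periods$start[i], periods$end[i] - 1, by = "day")
    age <- age_at(by, days)
    tab <- table(as.character(age_band(age)))
    acc[names(tab)] <- acc[names(tab)] + as.numeric(tab) / 365.25
  }
  tibble::tibble(band = factor(age_band_levels(), age_band_levels()),
                 person_years = unname(acc))
}

# row-by-row scan for a caution hit with explicit date comparisons
oracle_match_caution <- function(events, spec, index_date, registration_date,
                                 up_to_standard_date) {
  best <- as.Date(NA)
  for (i in seq_len(nrow(events))) {
    row <- events[i, ]
    is_match <- FALSE
    for (j in seq_len(nrow(spec$codes))) {
      c1 <- row$code; c2 <- spec$codes$code[j]
      if (row$coding_system == spec$codes$system[j]) {
        if (row$coding_system == "ICD10") {
          c1 <- toupper(gsub(".", "", c1, fixed = TRUE))
          c2 <- toupper(gsub(".", "", c2, fixed = TRUE))
        }
        if (c1 == c2) is_match <- TRUE
      }
    }
    if (!is_match) next
    d <- row$event_date
    ok <- if (spec$window_kind == "ANY_BEFORE") {
      d >= up_to_standard_date && d < index_date
    } else {
      k <- if (spec$window_kind == "YEARS_BEFORE") {
        12L * spec$window_length
      } else {
        spec$window_length
      }
      d >= oracle_shift_months(index_date, -k) && d < index_date &&
        d >= oracle_shift_months(registration_date, 12L)
    }
    if (ok && (is.na(best) || d < best)) best <- d
  }
  best
}

# numerical inversion of the Poisson CDF over the mean (independent of
# the chi-square closed form): bounds solve P(X >= x | mu_lo) = a/2 and
# P(X <= x | mu_hi) = a/2
oracle_poisson_ci <- function(x, conf = 0.95) {
  a <- 1 - conf
  lo <- if (x == 0) 0 else {
    stats::uniroot(function(mu) stats::ppois(x - 1, mu, lower.tail = FALSE) - a / 2,
                   c(1e-12, x + 1), tol = 1e-12)$root
  }
  hi <- stats::uniroot(function(mu) stats::ppois(x, mu) - a / 2,
                       c(x + 1e-9, 10 * x + 50), tol = 1e-12)$root
  c(lo, hi)
}

flat_rates <- function(rate) {
  stats::setNames(rep(rate, length(age_band_levels())), age_band_levels())
}

no_cautions <- function() {
  tibble::tibble(condition = character(), prevalence = numeric())
}

zero_bands <- function() flat_rates(0)
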