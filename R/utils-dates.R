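# Date, age-band, and rounding helpers shared across the pipeline.
#
# Birth is recorded as a year only (the primary-care database convention);
# an exact birthdate of 1 July of the birth year is imputed everywhere, so
# all age computations are deterministic and unbiased at mid-year.

#' Imputed birthdate from a year of birth
#'
#' Patients carry a year of birth only; 1 July of that year is imputed as
#' the exact birthdate for every age computation in the package.
#'
#' @param birth_year Integer vector of birth years.
#' @return A `Date` vector (1 July of each year).
#' @export
imputed_birthdate <- function(birth_year) {
  lubridate::make_date(birth_year, 7L, 1L)
}

#' Add calendar months with day clamping
#'
#' Calendar-month arithmetic in which an out-of-range day is clamped to the
#' last day of the target month (e.g. 2014-02-28 plus 12 months is
#' 2015-02-28, and 2014-03-31 minus 1 month is 2014-02-28). Thin wrapper
#' over [lubridate::add_with_rollback()] semantics via `%m+%`.
#'
#' @param date A `Date` vector.
#' @param n Number of months (may be negative).
#' @return A `Date` vector.
#' @export
add_months <- function(date, n) {
  date %m+% months(as.integer(n))
}

#' Completed age in years at a date
#'
#' Age in completed years at `date` for a patient born in `birth_year`,
#' using the imputed 1 July birthdate.
#'
#' @param birth_year Integer vector of birth years.
#' @param date A `Date` vector (recycled against `birth_year`).
#' @return Integer vector of completed ages.
#' @export
age_at <- function(birth_year, date) {
  # with a 1 July birthday, the birthday has passed iff month >= July
  lubridate::year(date) - as.integer(birth_year) -
    as.integer(lubridate::month(date) < 7L)
}

# Lower edges of the five-year age bands: 18-19, 20-24, ..., 90-94, 95+.
# The bottom band is two years wide (adults only) and the top band is open.
band_lower_edges <- function() c(18L, seq(20L, 95L, by = 5L))

#' Age-band labels used throughout the package
#'
#' Five-year adult age bands `"18-19"`, `"20-24"`, ..., `"90-94"`, `"95+"`.
#'
#' @return Character vector of band labels, youngest first.
#' @export
age_band_levels <- function() {
  lo <- band_lower_edges()
  hi <- c(lo[-1] - 1L, NA)
  ifelse(is.na(hi), paste0(lo, "+"), paste0(lo, "-", hi))
}

#' Assign ages to five-year bands
#'
#' @param age Integer vector of completed ages (must be >= 18).
#' @return Factor with levels [age_band_levels()].
#' @export
age_band <- function(age) {
  if (any(age < 18, na.rm = TRUE)) {
    abort("age_band(): ages below 18 are outside the adult band scheme")
  }
  idx <- findInterval(age, band_lower_edges())
  factor(age_band_levels()[idx], levels = age_band_levels())
}

# Round half away from zero (base round() is round-half-even).
# Report percentages and extrapolated pool sizes use this convention.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# days between two Dates as a plain numeric
days_between <- function(from, to) as.numeric(to - from)
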