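# Clinical code lists: one CSV row per (condition, code, system), with the
# condition's lookback window and consensus recruitment status repeated on
# each row. Three roles: the index disease definition, the treatment
# cautions, and dementia.

CODING_SYSTEMS <- c("READ", "ICD10", "OPCS", "PRODUCT")
WINDOW_KINDS <- c("ANY_BEFORE", "MONTHS_BEFORE", "YEARS_BEFORE")
RECRUITMENT_LEVELS <- c("POSSIBLE", "WITH_CAUTION", "UNLIKELY")
CODELIST_ROLES <- c("disease", "caution", "dementia")

#' Normalize a clinical code for matching
#'
#' ICD-10 codes are matched on the normalized form: dot removed and
#' upper-cased, so `"L12.0"` and `"l120"` are the same code. Read, OPCS and
#' product codes are matched case-sensitively on the exact string.
#'
#' @param code Character vector of codes.
#' @param system Matching character vector of coding systems
#'   (`"READ"`, `"ICD10"`, `"OPCS"`, `"PRODUCT"`).
#' @return Character vector of normalized codes.
#' @export
normalize_code <- function(code, system) {
  out <- code
  icd <- which(system == "ICD10")
  out[icd] <- toupper(gsub(".", "", code[icd], fixed = TRUE))
  out
}

#' Read a code-list collection from CSV
#'
#' The CSV has one row per (condition, code, system) with columns
#' `role` (`disease`/`caution`/`dementia`), `condition`, `code`, `system`,
#' `window_kind` (`ANY_BEFORE`/`MONTHS_BEFORE`/`YEARS_BEFORE`),
#' `window_length` (empty for `ANY_BEFORE`), `status` (consensus
#' recruitment status, cautions only) and `is_history` (logical: code text
#' states "history of" or similar). Duplicate (condition, code, system)
#' rows are collapsed with a warning. Windows on the disease row are
#' ignored; the disease and dementia entries must not share a name with
#' any caution.
#'
#' @param path Path to the CSV file.
#' @return A `codelist_collection`: list with tibbles `conditions`
#'   (condition, role, window_kind, window_length, status) and `codes`
#'   (condition, code, system, is_history).
#' @export
read_codelists <- function(path) {
  if (!file.exists(path)) abort(paste0("code-list file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    role = readr::col_character(),
    condition = readr::col_character(),
    code = readr::col_character(),
    system = readr::col_character(),
    window_kind = readr::col_character(),
    window_length = readr::col_integer(),
    status = readr::col_character(),
    is_history = readr::col_logical()
  ))
  validate_codelist_rows(raw, path)
  dup <- raw |> count(.data$condition, .data$code, .data$system) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(paste0(
      "collapsing ", sum(dup$n) - nrow(dup), " duplicate code row(s) in ", path,
      " (e.g. ", dup$condition[1], " / ", dup$code[1], ")"
    ))
    raw <- raw |> distinct(.data$condition, .data$code, .data$system, .keep_all = TRUE)
  }
  new_codelist_collection(raw)
}

validate_codelist_rows <- function(raw, path) {
  required <- c("role", "condition", "code", "system", "window_kind",
                "window_length", "status", "is_history")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("code-list file ", path, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(paste0("code-list file ", path, " is empty"))
  line <- function(i) paste0(path, " row ", i + 1L)  # +1 for header
  bad <- which(!raw$system %in% CODING_SYSTEMS)
  if (length(bad) > 0) {
    abort(paste0("unknown coding system '", raw$system[bad[1]], "' at ", line(bad[1])))
  }
  bad <- which(!raw$role %in% CODELIST_ROLES)
  if (length(bad) > 0) {
    abort(paste0("unknown role '", raw$role[bad[1]], "' at ", line(bad[1])))
  }
  bad <- which(!raw$window_kind %in% WINDOW_KINDS & raw$role == "caution")
  if (length(bad) > 0) {
    abort(paste0("unknown window kind '", raw$window_kind[bad[1]], "' at ", line(bad[1])))
  }
  bad <- which(raw$role == "caution" & raw$window_kind != "ANY_BEFORE" &
                 (is.na(raw$window_length) | raw$window_length <= 0))
  if (length(bad) > 0) {
    abort(paste0("caution '", raw$condition[bad[1]],
                 "' has a time-limited window without a positive length at ", line(bad[1])))
  }
  bad <- which(raw$role == "caution" & raw$window_kind == "ANY_BEFORE" &
                 !is.na(raw$window_length))
  if (length(bad) > 0) {
    abort(paste0("caution '", raw$condition[bad[1]],
                 "' has ANY_BEFORE with a window length at ", line(bad[1])))
  }
  bad <- which(raw$role == "caution" & !raw$status %in% RECRUITMENT_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("invalid recruitment status '", raw$status[bad[1]], "' at ", line(bad[1])))
  }
  if (!any(raw$role == "caution")) {
    abort(paste0("code-list file ", path, " contains no caution entries"))
  }
  if (!any(raw$role == "disease")) {
    abort(paste0("code-list file ", path, " contains no disease definition"))
  }
}

new_codelist_collection <- function(raw) {
  conditions <- raw |>
    distinct(.data$condition, .data$role, .data$window_kind,
             .data$window_length, .data$status)
  special <- conditions$condition[conditions$role != "caution"]
  cautions <- conditions$condition[conditions$role == "caution"]
  clash <- intersect(special, cautions)
  if (length(clash) > 0) {
    abort(paste0("'", clash[1], "' is both a caution and a disease/dementia entry"))
  }
  if (anyDuplicated(conditions$condition) > 0) {
    d <- conditions$condition[duplicated(conditions$condition)][1]
    abort(paste0("condition '", d, "' appears with inconsistent window/status/role rows"))
  }
  codes <- raw |>
    transmute(.data$condition, .data$code, .data$system,
              is_history = ifelse(is.na(.data$is_history), FALSE, .data$is_history))
  structure(
    list(conditions = as_tibble(conditions), codes = as_tibble(codes)),
    class = "codelist_collection"
  )
}

#' @export
print.codelist_collection <- function(x, ...) {
  n_cau <- sum(x$conditions$role == "caution")
  cat("<codelist_collection>: ", n_cau, " cautions, ",
      nrow(x$codes), " codes\n", sep = "")
  print(x$conditions, n = Inf)
  invisible(x)
}

#' Write a code-list collection back to CSV
#'
#' Inverse of [read_codelists()]: writing then reading reproduces the
#' collection exactly.
#'
#' @param collection A `codelist_collection`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_codelists <- function(collection, path) {
  stopifnot(inherits(collection, "codelist_collection"))
  out <- collection$codes |>
    left_join(collection$conditions, by = "condition") |>
    select("role", "condition", "code", "system",
           "window_kind", "window_length", "status", "is_history")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Extract one condition's specification from a collection
#'
#' @param collection A `codelist_collection`.
#' @param condition Condition name; or `role = "disease"`/`"dementia"` to
#'   pick the special entries by role.
#' @param role Optional role to select by instead of a name.
#' @return A list with `condition`, `window_kind`, `window_length`,
#'   `status` and a `codes` tibble (code, system, is_history), usable as a
#'   caution specification in [match_caution()].
#' @export
codelist_spec <- function(collection, condition = NULL, role = NULL) {
  stopifnot(inherits(collection, "codelist_collection"))
  cond <- collection$conditions
  if (!is.null(role)) {
    cond <- cond |> filter(.data$role == !!role)
    if (nrow(cond) == 0) abort(paste0("no entry with role '", role, "'"))
    condition <- cond$condition[1]
  }
  row <- collection$conditions |> filter(.data$condition == !!condition)
  if (nrow(row) == 0) abort(paste0("no condition '", condition, "' in collection"))
  list(
    condition = row$condition,
    window_kind = row$window_kind,
    window_length = row$window_length,
    status = row$status,
    codes = collection$codes |> filter(.data$condition == !!condition) |>
      select("code", "system", "is_history")
  )
}

#' Names of the caution conditions in a collection
#' @param collection A `codelist_collection`.
#' @return Character vector of caution condition names.
#' @export
caution_names <- function(collection) {
  collection$conditions$condition[collection$conditions$role == "caution"]
}

#' Drop "history of" codes from time-limited cautions
#'
#' Codes whose text states "history of" (or similar) date the recording,
#' not the event, so they cannot support a time-limited lookback; they are
#' removed from every caution whose window is not `ANY_BEFORE`. History
#' codes are marked by the explicit `is_history` column, not inferred from
#' code text. `ANY_BEFORE` entries, the disease definition, and dementia
#' are returned unchanged.
#'
#' @param collection A `codelist_collection`.
#' @return A `codelist_collection` with the flagged codes removed.
#' @export
strip_history_codes <- function(collection) {
  stopifnot(inherits(collection, "codelist_collection"))
  limited <- collection$conditions |>
    filter(.data$role == "caution", .data$window_kind != "ANY_BEFORE") |>
    pull(.data$condition)
  codes <- collection$codes |>
    filter(!(.data$condition %in% limited & .data$is_history))
  emptied <- setdiff(limited, unique(codes$condition))
  if (length(emptied) > 0) {
    abort(paste0("stripping history codes left '", emptied[1], "' with no codes"))
  }
  out <- collection
  out$codes <- codes
  out
}

#' Path to the bundled synthetic code lists, survey, and population table
#'
#' The package ships small plain-text fixtures: synthetic code lists for
#' the index disease, 22 treatment cautions and dementia (`codelists`);
#' a synthetic 13-grader consensus survey consistent with the published
#' recruitment statuses (`survey`); and an example national adult
#' population table by five-year age band (`population`). Codes are short
#' synthetic values; licensed Read/ICD-10 dictionaries are a drop-in
#' replacement with the same CSV schema.
#'
#' @param which One of `"codelists"`, `"survey"`, `"population"`.
#' @return Path to the installed CSV.
#' @export
trialpool_example <- function(which = c("codelists", "survey", "population")) {
  which <- match.arg(which)
  file <- switch(which,
    codelists = "codelists_synthetic.csv",
    survey = "survey_synthetic.csv",
    population = "population_england_example.csv"
  )
  system.file("extdata", file, package = "trialpool", mustWork = TRUE)
}
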