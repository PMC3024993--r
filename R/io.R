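#' Column schemas for admission and death extracts
#'
#' The expected CSV layouts for hospital separation records and death
#' records. `status_code`, `seifa_quintile` and `aria_category` may be empty.
#'
#' @return Named character vector mapping column name to type
#'   (`"character"`, `"date"`, `"integer"`, `"logical"`).
#' @export
admissions_schema <- function() {
  c(person_id = "character", admission_date = "date",
    separation_date = "date", principal_dx = "character",
    icd_version = "character", sector = "character", same_day = "logical",
    status_code = "integer", status_era = "character", sex = "character",
    age_years = "integer", region = "character", seifa_quintile = "integer",
    aria_category = "integer")
}

#' @rdname admissions_schema
#' @export
deaths_schema <- function() {
  c(person_id = "character", death_date = "date",
    status_code = "integer", status_era = "character")
}

schema_cols <- function(schema) {
  types <- list(character = readr::col_character(), date = readr::col_date(),
                integer = readr::col_integer(), logical = readr::col_logical())
  do.call(readr::cols, c(purrr::map(schema, ~ types[[.x]]),
                         list(.default = readr::col_skip())))
}

#' Read and validate a hospital admissions extract
#'
#' Reads a CSV of hospital separation records, checks each row against the
#' schema and record invariants, and returns the valid rows as a tibble.
#' Administrative extracts are frequently dirty, so validation collects
#' problems into a report by default (retrieved with [validation_report()])
#' and drops only the offending rows; `strict = TRUE` aborts on the first
#' problem instead.
#'
#' Row checks: parseable dates, `separation_date >= admission_date`,
#' `same_day` consistent with the dates, admissible sector / era / sex /
#' region labels, non-negative age, status code within its era's domain, and
#' SEIFA / ARIA in 1-5 when present.
#'
#' @param path Path to a CSV file with the [admissions_schema()] columns.
#' @param strict Abort on the first invalid row instead of collecting?
#' @return A tibble of valid [admissions_schema()] rows with a
#'   `validation_report` attribute (tibble of `row`, `person_id`, `problem`).
#' @export
read_admissions <- function(path, strict = FALSE) {
  df <- read_schema_csv(path, admissions_schema())
  validate_admissions(df, strict = strict)
}

#' Read and validate a deaths extract
#'
#' As [read_admissions()], for death records. A duplicated `person_id` is an
#' error in either mode: at most one death record per person is a structural
#' invariant of the linked extract, not a row-level defect.
#'
#' @param path Path to a CSV file with the [deaths_schema()] columns.
#' @param strict Abort on the first invalid row instead of collecting?
#' @return A tibble of valid [deaths_schema()] rows with a
#'   `validation_report` attribute.
#' @export
read_deaths <- function(path, strict = FALSE) {
  df <- read_schema_csv(path, deaths_schema())
  validate_deaths(df, strict = strict)
}

read_schema_csv <- function(path, schema) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(names(schema), header)
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Missing mandatory column(s) in %s: %s.", path,
              paste(missing, collapse = ", ")),
      class = "ascertain_schema_error"
    )
  }
  readr::read_csv(path, col_types = schema_cols(schema), na = c("", "NA"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Validate in-memory extracts
#'
#' The row-level checks behind [read_admissions()] and [read_deaths()],
#' applicable to tibbles constructed in code.
#'
#' @param df Tibble in the corresponding schema.
#' @param strict Abort on the first invalid row instead of collecting?
#' @return The valid rows, with a `validation_report` attribute.
#' @export
validate_admissions <- function(df, strict = FALSE) {
  df <- tibble::as_tibble(df)
  problems <- list(
    unparseable_admission_date = is.na(df$admission_date),
    unparseable_separation_date = is.na(df$separation_date),
    separation_before_admission =
      !is.na(df$admission_date) & !is.na(df$separation_date) &
      df$separation_date < df$admission_date,
    same_day_inconsistent =
      !is.na(df$admission_date) & !is.na(df$separation_date) &
      !is.na(df$same_day) &
      (df$same_day != (df$admission_date == df$separation_date)),
    invalid_sector = is.na(df$sector) | !df$sector %in% c("PUBLIC", "PRIVATE"),
    invalid_icd_version =
      is.na(df$icd_version) | !df$icd_version %in% c("ICD9CM", "ICD10AM"),
    invalid_sex = is.na(df$sex) | !df$sex %in% c("M", "F"),
    invalid_region = is.na(df$region) | !df$region %in% c("METRO", "NON_METRO"),
    negative_age = is.na(df$age_years) | df$age_years < 0,
    invalid_status_era = is.na(df$status_era) | !df$status_era %in% status_eras(),
    status_code_outside_era = status_code_invalid(df$status_code, df$status_era),
    seifa_out_of_range = !is.na(df$seifa_quintile) & !df$seifa_quintile %in% 1:5,
    aria_out_of_range = !is.na(df$aria_category) & !df$aria_category %in% 1:5
  )
  apply_validation(df, problems, strict, what = "admissions")
}

#' @rdname validate_admissions
#' @export
validate_deaths <- function(df, strict = FALSE) {
  df <- tibble::as_tibble(df)
  dup <- duplicated(df$person_id)
  if (any(dup)) {
    rlang::abort(
      sprintf("Duplicate death record(s) for person_id: %s.",
              paste(unique(df$person_id[dup]), collapse = ", ")),
      class = "ascertain_validation_error"
    )
  }
  problems <- list(
    unparseable_death_date = is.na(df$death_date),
    invalid_status_era = is.na(df$status_era) | !df$status_era %in% status_eras(),
    status_code_outside_era = status_code_invalid(df$status_code, df$status_era)
  )
  apply_validation(df, problems, strict, what = "deaths")
}

status_code_invalid <- function(code, era) {
  ok_era <- !is.na(era) & era %in% status_eras()
  bad <- rep(FALSE, length(code))
  legacy <- ok_era & era == "legacy_binary"
  bad[legacy] <- is.na(code[legacy]) | !code[legacy] %in% c(1L, 2L)
  four <- ok_era & era == "four_category"
  bad[four] <- !is.na(code[four]) & !code[four] %in% 1:4
  bad
}

apply_validation <- function(df, problems, strict, what) {
  report <- purrr::imap(problems, function(flag, name) {
    idx <- which(flag)
    tibble::tibble(row = idx, person_id = df$person_id[idx], problem = name)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$row)
  if (strict && nrow(report) > 0) {
    first <- report[1, ]
    rlang::abort(
      sprintf("Invalid %s row %d (person %s): %s.", what, first$row,
              first$person_id, first$problem),
      class = "ascertain_validation_error"
    )
  }
  keep <- !seq_len(nrow(df)) %in% report$row
  out <- df[keep, , drop = FALSE]
  attr(out, "validation_report") <- report
  out
}

#' Retrieve the validation report attached by a reader
#'
#' @param x A tibble returned by [read_admissions()], [read_deaths()],
#'   [validate_admissions()] or [validate_deaths()].
#' @return A tibble with columns `row`, `person_id`, `problem` (empty when
#'   all rows were valid).
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation_report")
  if (is.null(rep)) {
    rep <- tibble::tibble(row = integer(), person_id = character(),
                          problem = character())
  }
  rep
}

#' Write extracts in the canonical CSV schemas
#'
#' Writers matched to [read_admissions()] / [read_deaths()]: ISO-8601 dates,
#' empty fields for absent values, so that write-then-read is the identity
#' on valid collections.
#'
#' @param df Tibble in the corresponding schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(df, path) {
  readr::write_csv(df[, names(admissions_schema())], path, na = "")
  invisible(path)
}

#' @rdname write_admissions
#' @export
write_deaths <- function(df, path) {
  readr::write_csv(df[, names(deaths_schema())], path, na = "")
  invisible(path)
}
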