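#' Cohort definition
#'
#' Parameters defining the study cohort: the index window, eligible ages,
#' qualifying principal-diagnosis prefixes, the index sector, the lookback
#' depth, and the routine-dialysis exclusion codes. The defaults encode a
#' cardiovascular public-hospital cohort: separations during 2000-2005, ages
#' 25-74, ICD-10-AM chapter I (circulatory disease), a 20-year lookback, and
#' exclusion of same-day separations for routine dialysis (ICD-9-CM V56,
#' ICD-10-AM Z49).
#'
#' Diagnosis matching is by string prefix on the normalised code (upper case,
#' dots stripped), so `"I"` covers I00-I99 and `"Z49"` covers Z49.x.
#'
#' @param window_start,window_end Index window (coerced with [as.Date()]).
#' @param age_min,age_max Eligible age range at the qualifying admission.
#' @param dx_prefixes Character vector of qualifying diagnosis prefixes.
#' @param index_sector Hospital sector required for the index admission.
#' @param lookback_years Depth of the admission history, in years before the
#'   index admission date (window half-open on the left, closed at index).
#' @param dialysis_codes Prefixes whose same-day separations are excluded
#'   from the lookback.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(window_start = "2000-01-01", window_end = "2005-12-31",
                        age_min = 25, age_max = 74, dx_prefixes = "I",
                        index_sector = "PUBLIC", lookback_years = 20,
                        dialysis_codes = c("V56", "Z49")) {
  spec <- list(
    window_start = as.Date(window_start), window_end = as.Date(window_end),
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    dx_prefixes = toupper(as.character(dx_prefixes)),
    index_sector = match.arg(index_sector, c("PUBLIC", "PRIVATE")),
    lookback_years = as.integer(lookback_years),
    dialysis_codes = toupper(as.character(dialysis_codes))
  )
  if (spec$window_start > spec$window_end) {
    rlang::abort("`window_start` must not be after `window_end`.")
  }
  if (spec$age_min > spec$age_max) {
    rlang::abort("`age_min` must not exceed `age_max`.")
  }
  if (spec$lookback_years <= 0) {
    rlang::abort("`lookback_years` must be positive.")
  }
  structure(spec, class = "cohort_spec")
}

#' Read or write a cohort definition as JSON
#'
#' @param path JSON file holding any subset of the [cohort_spec()] fields;
#'   unspecified fields take their defaults.
#' @return `cohort_spec_from_json()`: a `cohort_spec`.
#' @export
cohort_spec_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(cfg), names(formals(cohort_spec)))
  if (length(extra) > 0) {
    rlang::abort(sprintf("Unknown cohort_spec field(s): %s.",
                         paste(extra, collapse = ", ")))
  }
  do.call(cohort_spec, cfg)
}

#' @rdname cohort_spec_from_json
#' @param spec A `cohort_spec`.
#' @export
cohort_spec_to_json <- function(spec, path) {
  jsonlite::write_json(lapply(unclass(spec), as.character), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  index window: %s to %s (%s sector)\n",
              x$window_start, x$window_end, x$index_sector))
  cat(sprintf("  ages %d-%d; dx prefixes: %s\n", x$age_min, x$age_max,
              paste(x$dx_prefixes, collapse = ", ")))
  cat(sprintf("  lookback %d years; same-day dialysis exclusions: %s\n",
              x$lookback_years, paste(x$dialysis_codes, collapse = ", ")))
  invisible(x)
}

normalise_dx <- function(dx) gsub(".", "", toupper(dx), fixed = TRUE)

has_prefix <- function(dx, prefixes) {
  dx <- normalise_dx(dx)
  Reduce(`|`, lapply(prefixes, function(p) startsWith(dx, p)),
         init = rep(FALSE, length(dx)))
}

#' Select index admissions
#'
#' For each person with at least one admission satisfying the cohort window
#' (separation date inside it), age range, sector, and principal-diagnosis
#' prefix, returns the admission with the most recent separation date. Ties
#' are broken by the latest admission date, then by stable input order
#' (first qualifying row wins). Persons with no qualifying admission are
#' absent from the result.
#'
#' @param admissions Validated admissions tibble.
#' @param spec A [cohort_spec()].
#' @return Tibble of index admissions, one row per person, carrying a
#'   `record_id` column (input row number) used downstream to mark the index
#'   record inside the history.
#' @export
select_index <- function(admissions, spec = cohort_spec()) {
  admissions |>
    dplyr::mutate(record_id = dplyr::row_number()) |>
    dplyr::filter(
      .data$separation_date >= spec$window_start,
      .data$separation_date <= spec$window_end,
      .data$sector == spec$index_sector,
      .data$age_years >= spec$age_min,
      .data$age_years <= spec$age_max,
      has_prefix(.data$principal_dx, spec$dx_prefixes)
    ) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::arrange(dplyr::desc(.data$separation_date),
                   dplyr::desc(.data$admission_date), .data$record_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$person_id)
}

#' Assemble lookback admission histories
#'
#' For each indexed person, collects all admissions — any cause, public and
#' private — whose admission date lies in the half-open window
#' `(index_date - lookback_years, index_date]`, excluding same-day
#' separations for routine dialysis (same-day flag set AND principal
#' diagnosis matching a dialysis exclusion prefix). The index record itself
#' is always included and marked with `is_index`.
#'
#' @param admissions Validated admissions tibble.
#' @param index Output of [select_index()].
#' @param spec A [cohort_spec()].
#' @return Tibble of history records, chronologically sorted within person,
#'   with columns `record_id` and `is_index` added.
#' @export
build_lookback <- function(admissions, index, spec = cohort_spec()) {
  idx <- index |>
    dplyr::select("person_id", index_record_id = "record_id",
                  index_date = "admission_date")
  admissions |>
    dplyr::mutate(record_id = dplyr::row_number()) |>
    dplyr::inner_join(idx, by = "person_id") |>
    dplyr::mutate(is_index = .data$record_id == .data$index_record_id) |>
    dplyr::filter(
      .data$admission_date > .data$index_date %m-%
        lubridate::years(spec$lookback_years),
      .data$admission_date <= .data$index_date,
      .data$is_index |
        !(.data$same_day & has_prefix(.data$principal_dx, spec$dialysis_codes))
    ) |>
    dplyr::select(-"index_record_id", -"index_date") |>
    dplyr::arrange(.data$person_id, .data$admission_date,
                   .data$separation_date, .data$record_id)
}

#' Attach subsequent death records
#'
#' A death record is attached to an indexed person when its date falls on or
#' after the index separation date and within the study window. Deaths for
#' persons without an index admission are ignored (such persons are never
#' part of the cohort); deaths predating the index separation or falling
#' after the window close are not attached and are logged as anomalies.
#'
#' @param index Output of [select_index()].
#' @param deaths Validated deaths tibble.
#' @param spec A [cohort_spec()].
#' @return A list with `deaths` (attached death records, one row per
#'   deceased person) and `anomalies` (tibble of `person_id`, `death_date`,
#'   `reason`).
#' @export
attach_deaths <- function(index, deaths, spec = cohort_spec()) {
  linked <- deaths |>
    dplyr::inner_join(
      dplyr::select(index, "person_id",
                    index_separation = "separation_date"),
      by = "person_id"
    )
  anomalies <- linked |>
    dplyr::filter(.data$death_date < .data$index_separation |
                    .data$death_date > spec$window_end) |>
    dplyr::mutate(reason = dplyr::if_else(
      .data$death_date < .data$index_separation,
      "death_predates_index_separation", "death_after_window_end"
    )) |>
    dplyr::select("person_id", "death_date", "reason")
  attached <- linked |>
    dplyr::filter(.data$death_date >= .data$index_separation,
                  .data$death_date <= spec$window_end) |>
    dplyr::select(-"index_separation")
  list(deaths = attached, anomalies = anomalies)
}

#' Build a linked cohort from admission and death extracts
#'
#' Runs [select_index()], [build_lookback()] and [attach_deaths()] and
#' bundles the results. This is the unit handed to [classify_status()].
#'
#' @param admissions Validated admissions tibble (e.g. from
#'   [read_admissions()]).
#' @param deaths Optional validated deaths tibble; `NULL` for an
#'   admissions-only cohort.
#' @param spec A [cohort_spec()].
#' @return An object of class `linked_cohort`: a list with tibbles `index`,
#'   `history` (lookback including the index record), `deaths`, `anomalies`,
#'   and the `spec`.
#' @export
build_cohort <- function(admissions, deaths = NULL, spec = cohort_spec()) {
  index <- select_index(admissions, spec)
  history <- build_lookback(admissions, index, spec)
  if (is.null(deaths)) {
    att <- list(
      deaths = tibble::tibble(person_id = character(),
                              death_date = as.Date(character()),
                              status_code = integer(),
                              status_era = character()),
      anomalies = tibble::tibble(person_id = character(),
                                 death_date = as.Date(character()),
                                 reason = character())
    )
  } else {
    att <- attach_deaths(index, deaths, spec)
  }
  structure(
    list(index = index, history = history, deaths = att$deaths,
         anomalies = att$anomalies, spec = spec),
    class = "linked_cohort"
  )
}

#' @export
print.linked_cohort <- function(x, ...) {
  cat("<linked_cohort>\n")
  cat(sprintf("  %d persons; %d history records (%.1f per person)\n",
              nrow(x$index), nrow(x$history),
              ifelse(nrow(x$index) > 0, nrow(x$history) / nrow(x$index), 0)))
  cat(sprintf("  %d attached deaths; %d anomalies\n",
              nrow(x$deaths), nrow(x$anomalies)))
  invisible(x)
}
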