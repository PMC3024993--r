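#' Age-band presets
#'
#' Two band sets are in routine use: `"summary"` (0-34, 35-64, 65+), used
#' for stratified under-ascertainment summaries, and `"completeness"`
#' (00-24, 25-44, 45-64, >65), used for identifier-completeness audits.
#'
#' @param age Integer vector of ages in years.
#' @param preset `"summary"` or `"completeness"`.
#' @return Factor of age-band labels.
#' @export
age_band <- function(age, preset = c("summary", "completeness")) {
  preset <- match.arg(preset)
  if (preset == "summary") {
    cut(age, breaks = c(-Inf, 34, 64, Inf),
        labels = c("0-34", "35-64", "65+"))
  } else {
    cut(age, breaks = c(-Inf, 24, 44, 64, Inf),
        labels = c("00-24", "25-44", "45-64", ">65"))
  }
}

#' Completeness of the Indigenous-status identifier by stratum
#'
#' Audits missingness of the status flag over hospital history records
#' (index plus lookback), by region, age group, sex, and recording period
#' (pre-2000 versus the index window). One row per level of each requested
#' factor.
#'
#' @param history History records tibble (e.g. `cohort$history`); must carry
#'   the admissions schema columns.
#' @param by Factors to audit, any of `"region"`, `"age_band"`, `"sex"`,
#'   `"period"`.
#' @param period_break First calendar year of the late period.
#' @param tsi_as_positive Passed to [interpret_status()].
#' @return Tibble with columns `factor`, `level`, `n_records`,
#'   `n_missing_flag`, `pct_complete`.
#' @export
completeness_by_stratum <- function(history,
                                    by = c("region", "age_band", "sex",
                                           "period"),
                                    period_break = 2000,
                                    tsi_as_positive = TRUE) {
  by <- match.arg(by, several.ok = TRUE)
  recs <- history |>
    dplyr::mutate(
      flag = interpret_status(.data$status_code, .data$status_era,
                              hospital_source(.data$sector),
                              tsi_as_positive = tsi_as_positive),
      age_band = as.character(age_band(.data$age_years, "completeness")),
      period = dplyr::if_else(
        lubridate::year(.data$admission_date) < period_break,
        sprintf("pre-%d", period_break), sprintf("%d+", period_break)
      )
    )
  purrr::map(by, function(f) {
    recs |>
      dplyr::group_by(level = as.character(.data[[f]])) |>
      dplyr::summarise(
        n_records = dplyr::n(),
        n_missing_flag = sum(.data$flag == "missing"),
        .groups = "drop"
      ) |>
      dplyr::mutate(factor = f,
                    pct_complete = 100 * (1 - .data$n_missing_flag /
                                            .data$n_records)) |>
      dplyr::select("factor", "level", "n_records", "n_missing_flag",
                    "pct_complete")
  }) |>
    purrr::list_rbind()
}

#' Under-ascertainment by demographic factor
#'
#' Per level of a demographic factor (taken from the index admission):
#' persons identified under the index rule, persons identified under the
#' ever rule (any hospital record or death), and the relative increase of
#' ever over index — the stratum's under-ascertainment if ever-identified is
#' taken as the reference. Persons with an absent SEIFA or ARIA value form
#' an explicit `"unknown"` level.
#'
#' @param results An `ascertainment_results` tibble from [classify_status()].
#' @param factor One of `"sex"`, `"age_group"`, `"seifa"`, `"aria"`,
#'   `"region"`.
#' @param digits Decimal places (half-up) for the percentage; the
#'   conventional presentation is whole percent (`digits = 0`).
#' @return A tibble of class `stratum_summary` with columns `factor`,
#'   `level`, `index_count`, `ever_count`, `underestimate_pct`.
#' @export
underestimation_by_factor <- function(results,
                                      factor = c("sex", "age_group", "seifa",
                                                 "aria", "region"),
                                      digits = 0) {
  factor <- match.arg(factor)
  level <- switch(
    factor,
    sex = results$sex,
    age_group = as.character(age_band(results$age_years, "summary")),
    seifa = as.character(results$seifa_quintile),
    aria = as.character(results$aria_category),
    region = results$region
  )
  out <- results |>
    dplyr::mutate(level = dplyr::coalesce(level, "unknown")) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      index_count = sum(.data$index_pos),
      ever_count = sum(.data$ever_pos),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      factor = factor,
      underestimate_pct = dplyr::if_else(
        .data$index_count > 0,
        excess_pct(pmax(.data$index_count, 1L),
                   .data$ever_count - .data$index_count, digits = digits),
        NA_real_
      )
    ) |>
    dplyr::select("factor", "level", "index_count", "ever_count",
                  "underestimate_pct") |>
    dplyr::arrange(.data$level)
  tibble::new_tibble(out, class = "stratum_summary")
}

#' Compare under-ascertainment across strata
#'
#' Chi-square comparison of newly-identified versus index-identified counts
#' across the levels of a stratified summary: an r x 2 table (rows = levels,
#' columns = persons added by linkage vs persons already identified at
#' index) passed to [chi_square_test()].
#'
#' @param summaries A `stratum_summary` tibble from
#'   [underestimation_by_factor()].
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `min_expected`.
#' @export
compare_strata <- function(summaries) {
  if (nrow(summaries) < 2) {
    rlang::abort("At least two strata are required for comparison.")
  }
  m <- cbind(newly_identified = summaries$ever_count - summaries$index_count,
             index_identified = summaries$index_count)
  rownames(m) <- summaries$level
  chi_square_test(m)
}
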