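#' Apply the four status-determination rules to a linked cohort
#'
#' Determines each person's Indigenous status under four rules using
#' progressively more of the linked history:
#'
#' * **index**: positive flag on the index admission only (the most
#'   conservative rule and the baseline comparator);
#' * **index + death**: index admission or subsequent death record;
#' * **majority + death**: at least `majority_threshold` (default 50%) of
#'   hospital records with a stated flag — index plus 20-year lookback — are
#'   positive, or the death record is positive;
#' * **ever + death**: any hospital record, or the death record, is positive
#'   (the least conservative rule, "ever identified").
#'
#' Missing flags never count as positive or negative: they are excluded from
#' both numerator and denominator of the majority rule, and a person with no
#' stated hospital flag is classified by the death record alone. The death
#' record is an OR-term in the last three rules; it never enters the
#' majority denominator. An exact-threshold share counts as positive
#' ("at least 50%").
#'
#' @param cohort A `linked_cohort` from [build_cohort()].
#' @param majority_threshold Share of stated hospital flags that must be
#'   positive under the majority rule; default 0.5.
#' @param tsi_as_positive Passed to [interpret_status()].
#' @return A tibble of class `ascertainment_results`, one row per person:
#'   the four rule outcomes (`index_pos`, `index_or_death_pos`,
#'   `majority_pos`, `ever_pos`), their hospital-only parts
#'   (`majority_hmdc_pos`, `ever_hmdc_pos`), flag tallies
#'   (`n_flagged_records`, `n_positive_records`), the death flag, and the
#'   person's index-admission attributes (sex, age, region, SEIFA, ARIA).
#' @export
classify_status <- function(cohort, majority_threshold = 0.5,
                            tsi_as_positive = TRUE) {
  stopifnot(inherits(cohort, "linked_cohort"))

  per_person <- cohort$history |>
    dplyr::mutate(flag = interpret_status(
      .data$status_code, .data$status_era, hospital_source(.data$sector),
      tsi_as_positive = tsi_as_positive
    )) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_flagged_records = sum(.data$flag != "missing"),
      n_positive_records = sum(.data$flag == "positive"),
      index_pos = any(.data$is_index & .data$flag == "positive"),
      ever_hmdc_pos = .data$n_positive_records > 0,
      .groups = "drop"
    )

  death_flags <- cohort$deaths |>
    dplyr::mutate(death_flag = interpret_status(
      .data$status_code, .data$status_era, "death",
      tsi_as_positive = tsi_as_positive
    )) |>
    dplyr::select("person_id", "death_flag")

  attrs <- cohort$index |>
    dplyr::select("person_id", "sex", "age_years", "region",
                  "seifa_quintile", "aria_category",
                  index_separation = "separation_date")

  out <- per_person |>
    dplyr::left_join(death_flags, by = "person_id") |>
    dplyr::left_join(attrs, by = "person_id") |>
    dplyr::mutate(
      has_death = !is.na(.data$death_flag),
      death_pos = !is.na(.data$death_flag) & .data$death_flag == "positive",
      majority_hmdc_pos = .data$n_flagged_records > 0 &
        .data$n_positive_records >=
          majority_threshold * .data$n_flagged_records,
      index_or_death_pos = .data$index_pos | .data$death_pos,
      majority_pos = .data$majority_hmdc_pos | .data$death_pos,
      ever_pos = .data$ever_hmdc_pos | .data$death_pos
    ) |>
    dplyr::select(
      "person_id", "index_pos", "index_or_death_pos", "majority_pos",
      "ever_pos", "majority_hmdc_pos", "ever_hmdc_pos",
      "n_flagged_records", "n_positive_records", "death_flag", "death_pos",
      "has_death", "sex", "age_years", "region", "seifa_quintile",
      "aria_category", "index_separation"
    )
  tibble::new_tibble(out, class = "ascertainment_results")
}

hospital_source <- function(sector) {
  dplyr::if_else(sector == "PUBLIC", "hospital_public_wa", "hospital_other")
}

#' Tabulate ascertainment counts by determination rule
#'
#' Produces the three-column summary of persons identified as Aboriginal
#' under progressively more data: index admission only, index plus the
#' majority of the 20-year admission history, and index plus any record ever
#' positive — each split into cases found in morbidity records alone versus
#' added by death records. Derived rows give the excess over the index
#' baseline and the equivalent under-ascertainment of the baseline relative
#' to each revised count.
#'
#' @param results An `ascertainment_results` tibble from [classify_status()].
#' @return An `ascertainment_table` (see [ascertainment_table()]).
#' @export
tabulate_ascertainment <- function(results) {
  morbidity <- c(
    index = sum(results$index_pos),
    majority = sum(results$majority_hmdc_pos),
    ever = sum(results$ever_hmdc_pos)
  )
  death_alone <- c(
    index = sum(results$index_or_death_pos & !results$index_pos),
    majority = sum(results$majority_pos & !results$majority_hmdc_pos),
    ever = sum(results$ever_pos & !results$ever_hmdc_pos)
  )
  ascertainment_table(morbidity, death_alone)
}

#' Construct an ascertainment table from counts
#'
#' Builds the rule-by-source summary directly from counts, e.g. from a
#' published table. Counts are per determination rule (index, majority,
#' ever), split into persons identified in morbidity records alone and
#' persons added by death records; the combined count is their sum. The
#' baseline for the derived percentages is the index-rule morbidity-alone
#' count (identification on the unlinked index admission).
#'
#' @param morbidity_alone,death_alone Integer vectors of length 3 in rule
#'   order (index, majority, ever).
#' @param digits Decimal places (half-up) for the derived percentages.
#' @return A tibble of class `ascertainment_table` with columns `method`,
#'   `morbidity_alone`, `death_alone`, `combined`, `excess_pct` (combined
#'   over baseline) and `underestimate_pct` (baseline shortfall relative to
#'   combined).
#' @examples
#' ascertainment_table(c(3060, 3094, 3636), c(83, 78, 60))
#' @export
ascertainment_table <- function(morbidity_alone, death_alone, digits = 1) {
  stopifnot(length(morbidity_alone) == 3, length(death_alone) == 3,
            all(morbidity_alone >= 0), all(death_alone >= 0))
  morbidity_alone <- as.integer(morbidity_alone)
  death_alone <- as.integer(death_alone)
  combined <- morbidity_alone + death_alone
  baseline <- morbidity_alone[1]
  if (baseline > 0) {
    excess <- excess_pct(baseline, combined - baseline, digits = digits)
    underest <- underestimation_pct(baseline, combined, digits = digits)
  } else {
    excess <- underest <- rep(NA_real_, 3)
  }
  tibble::new_tibble(
    tibble::tibble(
      method = c("index", "majority", "ever"),
      morbidity_alone = morbidity_alone,
      death_alone = death_alone,
      combined = combined,
      excess_pct = excess,
      underestimate_pct = underest
    ),
    class = "ascertainment_table"
  )
}

#' Combined counts of the four determination rules
#'
#' The person counts identified under each of the four rules, in increasing
#' order of data used: index only, index or death, majority or death, ever
#' or death. Monotone non-decreasing by construction.
#'
#' @param results An `ascertainment_results` tibble.
#' @return Named integer vector of length 4.
#' @export
method_counts <- function(results) {
  c(index = sum(results$index_pos),
    index_death = sum(results$index_or_death_pos),
    majority_death = sum(results$majority_pos),
    ever_death = sum(results$ever_pos))
}
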