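#' Cross-tabulate death-record status against hospital-derived status
#'
#' For deceased cohort members, tabulates the death-record flag (positive /
#' negative / missing) against hospital-derived status: ever identified as
#' Aboriginal in hospital morbidity records (the ever rule restricted to
#' hospital records, excluding the death record itself to avoid
#' circularity) versus other. Derived quantities:
#'
#' * the total identified in either source (death-record positives plus
#'   hospital-positives among the other death-flag rows);
#' * under-ascertainment of the death-record count relative to that total,
#'   with its Wilson complement interval;
#' * per-row hospital-positive percentages with Wilson intervals;
#' * the informative-missingness relative risk: probability of being
#'   hospital-identified among deaths with a missing death flag versus
#'   deaths with a stated (positive or negative) flag, with Katz interval.
#'   A ratio above 1 indicates that missing death flags are enriched for
#'   people identified as Aboriginal elsewhere — missingness is informative.
#'
#' @param results An `ascertainment_results` tibble from [classify_status()].
#' @param conf_level Confidence level for the derived intervals.
#' @return An object of class `death_crosstab`; see
#'   [death_cross_tab_counts()] for its structure.
#' @export
death_cross_tab <- function(results, conf_level = 0.95) {
  dead <- dplyr::filter(results, .data$has_death)
  cells <- function(flag) {
    rows <- dead$death_flag == flag
    c(sum(rows & dead$ever_hmdc_pos), sum(rows & !dead$ever_hmdc_pos))
  }
  death_cross_tab_counts(positive = cells("positive"),
                         negative = cells("negative"),
                         missing = cells("missing"),
                         conf_level = conf_level)
}

#' Construct a death cross-tabulation from counts
#'
#' As [death_cross_tab()], but taking the six cell counts directly (e.g.
#' from a published table). Each argument is the pair (hospital-positive,
#' hospital-other) for one death-record flag row.
#'
#' @param positive,negative,missing Integer vectors of length 2:
#'   `c(hospital_positive, hospital_other)` for that death-flag row.
#' @param conf_level Confidence level for the derived intervals.
#' @return A `death_crosstab`: a list with
#'   \describe{
#'     \item{table}{tibble of rows `positive`, `negative`, `stated`
#'       (subtotal), `missing`, `total` with cell counts, row totals and
#'       hospital-positive row percentage with Wilson bounds;}
#'     \item{death_record_positive}{deaths flagged positive on the death
#'       record;}
#'     \item{identified_either}{deaths identified in either source;}
#'     \item{underestimate}{`ratio_estimate` of the death-record shortfall
#'       (Wilson complement percentage);}
#'     \item{missingness_rr}{`ratio_estimate` of the missing-vs-stated
#'       relative risk (Katz), or `NULL` when undefined.}
#'   }
#' @examples
#' death_cross_tab_counts(positive = c(654, 60), negative = c(188, 18048),
#'                        missing = c(73, 786))
#' @export
death_cross_tab_counts <- function(positive, negative, missing,
                                   conf_level = 0.95) {
  stopifnot(length(positive) == 2, length(negative) == 2,
            length(missing) == 2)
  m <- rbind(positive = as.integer(positive),
             negative = as.integer(negative),
             missing = as.integer(missing))
  stopifnot(all(m >= 0))
  colnames(m) <- c("hmdc_positive", "hmdc_other")
  stated <- m["positive", ] + m["negative", ]
  total <- stated + m["missing", ]

  row_tab <- tibble::tibble(
    death_flag = c("positive", "negative", "stated", "missing", "total"),
    hmdc_positive = unname(c(m["positive", 1], m["negative", 1], stated[1],
                             m["missing", 1], total[1])),
    hmdc_other = unname(c(m["positive", 2], m["negative", 2], stated[2],
                          m["missing", 2], total[2]))
  ) |>
    dplyr::mutate(
      total = .data$hmdc_positive + .data$hmdc_other,
      pct_hmdc_positive = NA_real_, pct_low = NA_real_, pct_high = NA_real_
    )
  for (i in seq_len(nrow(row_tab))) {
    if (row_tab$total[i] > 0) {
      w <- wilson_interval(row_tab$hmdc_positive[i], row_tab$total[i],
                           conf_level = conf_level)
      row_tab$pct_hmdc_positive[i] <- w$estimate * 100
      row_tab$pct_low[i] <- w$conf_low * 100
      row_tab$pct_high[i] <- w$conf_high * 100
    }
  }

  n_deaths <- sum(total)
  death_record_positive <- sum(m["positive", ])
  identified_either <- death_record_positive +
    m["negative", "hmdc_positive"] + m["missing", "hmdc_positive"]

  underestimate <- NULL
  if (identified_either > 0) {
    underestimate <- wilson_interval(death_record_positive, identified_either,
                                     conf_level = conf_level,
                                     complement = TRUE)
  }
  missingness_rr <- NULL
  n_missing <- sum(m["missing", ])
  if (n_missing > 0 && sum(stated) > 0 &&
      m["missing", "hmdc_positive"] > 0 && stated[["hmdc_positive"]] > 0) {
    missingness_rr <- relative_risk(
      m["missing", "hmdc_positive"], n_missing,
      stated[["hmdc_positive"]], sum(stated), conf_level = conf_level
    )
  }
  structure(
    list(table = row_tab, n_deaths = n_deaths,
         death_record_positive = death_record_positive,
         identified_either = identified_either,
         underestimate = underestimate,
         missingness_rr = missingness_rr,
         conf_level = conf_level),
    class = "death_crosstab"
  )
}

#' @export
print.death_crosstab <- function(x, digits = 1, ...) {
  cat("<death_crosstab>\n")
  if (x$n_deaths == 0) {
    cat("  no deaths: statistics undefined\n")
    return(invisible(x))
  }
  tab <- x$table |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("pct"),
                                ~ round_half_up(.x, digits)))
  print(tab)
  cat(sprintf("  deaths flagged positive on death record: %d\n",
              x$death_record_positive))
  cat(sprintf("  identified as Aboriginal in either source: %d\n",
              x$identified_either))
  if (!is.null(x$underestimate)) {
    cat(sprintf("  death-record under-ascertainment: %.1f%% (%.0f%% CI %.1f to %.1f)\n",
                round_half_up(x$underestimate$estimate, digits),
                100 * x$conf_level,
                round_half_up(x$underestimate$conf_low, digits),
                round_half_up(x$underestimate$conf_high, digits)))
  }
  if (is.null(x$missingness_rr)) {
    cat("  missingness relative risk: undefined\n")
  } else {
    cat(sprintf("  missingness relative risk: %.1f (%.0f%% CI %.1f to %.1f)\n",
                round_half_up(x$missingness_rr$estimate, digits),
                100 * x$conf_level,
                round_half_up(x$missingness_rr$conf_low, digits),
                round_half_up(x$missingness_rr$conf_high, digits)))
  }
  invisible(x)
}
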