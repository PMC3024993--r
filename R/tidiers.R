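#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ratio estimate
#'
#' @param x A `ratio_estimate` from [wilson_interval()] or
#'   [relative_risk()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `conf.level`, `method`.
#' @export
tidy.ratio_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$conf_low,
                 conf.high = x$conf_high, conf.level = x$conf_level,
                 method = x$method)
}

#' @rdname tidy.ratio_estimate
#' @export
glance.ratio_estimate <- function(x, ...) tidy.ratio_estimate(x)

#' Tidy an ascertainment table
#'
#' @param x An `ascertainment_table`.
#' @param ... Unused.
#' @return Long tibble with one row per rule and source
#'   (`morbidity_alone` / `death_alone` / `combined`).
#' @export
tidy.ascertainment_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("morbidity_alone", "death_alone", "combined"),
                        names_to = "source", values_to = "count")
}

#' @rdname tidy.ascertainment_table
#' @return `glance()`: one row with the combined count and derived
#'   percentage per rule, in wide form.
#' @export
glance.ascertainment_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("method", "combined", "excess_pct", "underestimate_pct") |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = c("combined", "excess_pct",
                                       "underestimate_pct"))
}

#' Tidy a death cross-tabulation
#'
#' @param x A `death_crosstab`.
#' @param ... Unused.
#' @return `tidy()`: the row-level table (cells, totals, row percentages
#'   with Wilson bounds). `glance()`: a one-row summary with the headline
#'   statistics (death-record positives, total identified in either source,
#'   under-ascertainment with CI, missingness relative risk with CI).
#' @export
tidy.death_crosstab <- function(x, ...) x$table

#' @rdname tidy.death_crosstab
#' @export
glance.death_crosstab <- function(x, ...) {
  u <- x$underestimate
  rr <- x$missingness_rr
  tibble::tibble(
    n_deaths = x$n_deaths,
    death_record_positive = x$death_record_positive,
    identified_either = x$identified_either,
    underestimate_pct = if (is.null(u)) NA_real_ else u$estimate,
    underestimate_low = if (is.null(u)) NA_real_ else u$conf_low,
    underestimate_high = if (is.null(u)) NA_real_ else u$conf_high,
    missingness_rr = if (is.null(rr)) NA_real_ else rr$estimate,
    missingness_rr_low = if (is.null(rr)) NA_real_ else rr$conf_low,
    missingness_rr_high = if (is.null(rr)) NA_real_ else rr$conf_high,
    conf_level = x$conf_level
  )
}
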