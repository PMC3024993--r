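#' Plot an ascertainment table
#'
#' Stacked bars of persons identified under each determination rule, split
#' into morbidity-only cases and cases added by death records.
#'
#' @param object An `ascertainment_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ascertainment_table <- function(object, ...) {
  df <- tidy.ascertainment_table(object) |>
    dplyr::filter(.data$source != "combined") |>
    dplyr::mutate(
      method = factor(.data$method, levels = c("index", "majority", "ever")),
      source = factor(.data$source,
                      levels = c("death_alone", "morbidity_alone"),
                      labels = c("added by death records",
                                 "morbidity records alone"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$count,
                                   fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "determination rule", y = "persons identified",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot stratified under-ascertainment
#'
#' Dot plot of the under-ascertainment percentage by stratum level.
#'
#' @param object A `stratum_summary` from [underestimation_by_factor()], or
#'   several row-bound together.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stratum_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$underestimate_pct,
                               y = .data$level)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$factor),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "under-ascertainment if ever-identified (%)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a death cross-tabulation
#'
#' Hospital-identified percentage per death-record flag row with Wilson
#' interval bars.
#'
#' @param object A `death_crosstab`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.death_crosstab <- function(object, ...) {
  df <- object$table |>
    dplyr::filter(.data$death_flag %in% c("negative", "stated", "missing"),
                  .data$total > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$death_flag,
                                   y = .data$pct_hmdc_positive)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pct_low,
                                        ymax = .data$pct_high),
                           width = 0.2) +
    ggplot2::labs(x = "status on death record",
                  y = "hospital-identified as Aboriginal (%)") +
    ggplot2::theme_minimal()
}

#' Plot a recovery report
#'
#' Recovered estimates with 3-SE Monte-Carlo error bars against their
#' configured / closed-form expectations.
#'
#' @param object A `recovery_report` from [recovery_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$quantity,
                                       y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - 3 * .data$mc_se,
                                        ymax = .data$estimate + 3 * .data$mc_se),
                           width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected),
                        shape = 4, size = 3, colour = "red") +
    ggplot2::labs(y = "estimate (3 MC SE) vs expectation (x)", x = NULL) +
    ggplot2::theme_minimal()
}
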