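#' Pipeline entry points
#'
#' High-level orchestration functions behind the command-line wrapper in
#' `inst/cli/ascertain.R`: generate a synthetic extract pair, analyse an
#' extract pair end to end, or run a parameter-recovery experiment. Each
#' writes its outputs under `out_dir` together with a structured run log
#' (seed, configuration hash, row-validation anomalies).
#'
#' @param out_dir Output directory (created if absent).
#' @param params A [simulation_params()] object.
#' @return `run_simulate()`: the `synthetic_cohort`, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, params = simulation_params()) {
  sim <- simulate_to_csv(params, out_dir)
  write_run_log(out_dir, "simulate", params$seed, unclass(params),
                anomalies = 0)
  invisible(sim)
}

#' @rdname pipeline
#' @param admissions_path CSV of hospital separations
#'   ([admissions_schema()]).
#' @param deaths_path Optional CSV of death records ([deaths_schema()]);
#'   `NULL` runs an admissions-only analysis (no death cross-tabulation)
#'   with a warning.
#' @param spec A [cohort_spec()].
#' @param conf_level Confidence level for interval estimates.
#' @param strict Passed to the readers.
#' @return `run_analyse()`: invisibly, a list with the cohort, per-person
#'   results and the three result tables. Writes `table1.csv` (rule-by-source
#'   counts), `table2.csv` (death cross-tabulation), `table3.csv`
#'   (stratified under-ascertainment), `estimates.csv` (interval estimates),
#'   `results.csv` (per-person determinations) and `run_log.txt`.
#' @export
run_analyse <- function(admissions_path, deaths_path = NULL, out_dir,
                        spec = cohort_spec(), conf_level = 0.95,
                        strict = FALSE) {
  admissions <- read_admissions(admissions_path, strict = strict)
  deaths <- NULL
  if (!is.null(deaths_path)) {
    deaths <- read_deaths(deaths_path, strict = strict)
  } else {
    rlang::warn("No deaths file supplied: running admissions-only analysis.")
  }
  n_invalid <- nrow(validation_report(admissions)) +
    if (is.null(deaths)) 0L else nrow(validation_report(deaths))

  cohort <- build_cohort(admissions, deaths, spec)
  results <- classify_status(cohort)
  table1 <- tabulate_ascertainment(results)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(table1, file.path(out_dir, "table1.csv"))
  readr::write_csv(results, file.path(out_dir, "results.csv"), na = "")

  estimates <- list()
  crosstab <- NULL
  if (!is.null(deaths) && nrow(cohort$deaths) > 0) {
    crosstab <- death_cross_tab(results, conf_level = conf_level)
    readr::write_csv(crosstab$table, file.path(out_dir, "table2.csv"))
    if (!is.null(crosstab$underestimate)) {
      estimates$death_underascertainment <- crosstab$underestimate
    }
    if (!is.null(crosstab$missingness_rr)) {
      estimates$missingness_rr <- crosstab$missingness_rr
    }
  }

  table3 <- purrr::map(
    c("sex", "age_group", "seifa", "aria", "region"),
    ~ underestimation_by_factor(results, .x)
  ) |> purrr::list_rbind()
  readr::write_csv(table3, file.path(out_dir, "table3.csv"))

  if (length(estimates) > 0) {
    est_tab <- purrr::imap(estimates, ~ dplyr::mutate(
      tidy_ratio_cols(.x), term = .y, .before = 1)) |>
      purrr::list_rbind()
    readr::write_csv(est_tab, file.path(out_dir, "estimates.csv"))
  }

  write_run_log(out_dir, "analyse", seed = NA,
                config = unclass(spec), anomalies = n_invalid,
                extra = sprintf("cohort: %d persons, %d history records, %d deaths",
                                nrow(cohort$index), nrow(cohort$history),
                                nrow(cohort$deaths)))
  invisible(list(cohort = cohort, results = results, table1 = table1,
                 crosstab = crosstab, table3 = table3))
}

#' @rdname pipeline
#' @param n_replicates Number of replicates for the recovery experiment.
#' @return `run_recover()`: the `recovery_report`, invisibly. Writes
#'   `recovery.csv`, `recovery_replicates.csv` and `run_log.txt`.
#' @export
run_recover <- function(out_dir, params = simulation_params(),
                        n_replicates = 1) {
  report <- recovery_experiment(params, n_replicates = n_replicates)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(report, file.path(out_dir, "recovery.csv"))
  readr::write_csv(attr(report, "replicates"),
                   file.path(out_dir, "recovery_replicates.csv"))
  write_run_log(out_dir, "recover", params$seed, unclass(params),
                anomalies = 0)
  invisible(report)
}

tidy_ratio_cols <- function(x) {
  dplyr::select(tibble::as_tibble(x), "estimate", "conf_low", "conf_high",
                "conf_level", "method")
}

write_run_log <- function(out_dir, command, seed, config, anomalies,
                          extra = NULL) {
  lines <- c(
    sprintf("command: %s", command),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", seed),
    sprintf("config_hash: %s", rlang::hash(config)),
    sprintf("row_validation_anomalies: %d", anomalies),
    extra
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
  invisible(lines)
}
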