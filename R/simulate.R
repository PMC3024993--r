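#' Simulation parameters for a synthetic linked cohort
#'
#' Defines the generative model for synthetic admission and death extracts
#' with the misclassification structure the ascertainment analysis assumes:
#'
#' * each person has a latent true Indigenous status (prevalence
#'   `prop_true_positive`) and a demographic stratum (sex, age, SEIFA
#'   quintile, ARIA remoteness category, region);
#' * every person receives one qualifying public-hospital cardiovascular
#'   index admission inside the study window, plus a truncated-Poisson
#'   number of lookback admissions (any cause, public or private) over the
#'   20 preceding years;
#' * each hospital record carries a recorded status flag: for a truly
#'   positive person the first record is positive with a stratum-dependent
#'   sensitivity, and each subsequent record copies the previous recorded
#'   flag with probability `within_person_correlation` (modelling the shared
#'   patient-management system that perpetuates earlier classifications) or
#'   is re-drawn; truly negative persons are flagged positive at a near-zero
#'   false-positive rate;
#' * hospital flags may be missing (emitted as an absent four-category code)
#'   on private-sector records only, at a configurable rate — in WA public
#'   hospitals "not stated" is keyed identically to "neither", so a missing
#'   public flag is not representable;
#' * deaths occur with status-dependent probability; the death-record flag
#'   is missing with status-dependent probability (informative missingness —
#'   the default ratio positive:negative is 1.9) and, when stated, positive
#'   with probability `death_flag_sensitivity` for truly positive persons;
#' * flags on records dated before 2000 are emitted in the legacy binary
#'   coding, later ones in the four-category coding, exercising the recode
#'   path.
#'
#' @param n_persons Number of persons; the default matches a state-wide
#'   cardiovascular cohort (62,692).
#' @param prop_true_positive Latent prevalence of true positive status.
#' @param admissions_per_person List with `mean`: the lookback admission
#'   count is Poisson(`mean`) truncated at >= 1.
#' @param sensitivity_by_stratum Either a single probability (constant
#'   sensitivity) or a tibble with columns `aria_category`, `age_band`,
#'   `seifa_quintile`, `sensitivity` covering every combination; see
#'   [default_sensitivity_map()].
#' @param false_positive_rate Per-record probability a truly negative
#'   person's record is flagged positive.
#' @param within_person_correlation Probability a record copies the person's
#'   previous recorded flag instead of being re-drawn.
#' @param death_prob_by_status Named vector `c(positive=, negative=)`:
#'   probability of death during follow-up.
#' @param death_flag_missing_prob_by_status Named vector
#'   `c(positive=, negative=)`: probability the death-record flag is
#'   missing. The default encodes a 1.9 positive:negative ratio.
#' @param death_flag_sensitivity Probability a stated death flag is positive
#'   for a truly positive person.
#' @param hmdc_missing_prob Probability a private-sector hospital record's
#'   flag is missing; a single value or a named vector by region
#'   (`METRO`, `NON_METRO`).
#' @param private_sector_prob Probability a lookback admission is
#'   private-sector.
#' @param dialysis_record_prob Probability a lookback admission is a
#'   same-day routine-dialysis separation (excluded by the cohort builder).
#' @param window_start,window_end Study window for index admissions.
#' @param lookback_years Depth of the simulated admission history.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_persons = 62692,
                              prop_true_positive = 0.06,
                              admissions_per_person = list(mean = 11),
                              sensitivity_by_stratum = default_sensitivity_map(),
                              false_positive_rate = 0.001,
                              within_person_correlation = 0.4,
                              death_prob_by_status =
                                c(positive = 0.35, negative = 0.31),
                              death_flag_missing_prob_by_status =
                                c(positive = 0.076, negative = 0.04),
                              death_flag_sensitivity = 0.73,
                              hmdc_missing_prob = 0,
                              private_sector_prob = 0.2,
                              dialysis_record_prob = 0.01,
                              window_start = "2000-01-01",
                              window_end = "2005-12-31",
                              lookback_years = 20,
                              seed = 1L) {
  params <- list(
    n_persons = as.integer(n_persons),
    prop_true_positive = prop_true_positive,
    admissions_per_person = admissions_per_person,
    sensitivity_by_stratum = sensitivity_by_stratum,
    false_positive_rate = false_positive_rate,
    within_person_correlation = within_person_correlation,
    death_prob_by_status = death_prob_by_status,
    death_flag_missing_prob_by_status = death_flag_missing_prob_by_status,
    death_flag_sensitivity = death_flag_sensitivity,
    hmdc_missing_prob = hmdc_missing_prob,
    private_sector_prob = private_sector_prob,
    dialysis_record_prob = dialysis_record_prob,
    window_start = as.Date(window_start),
    window_end = as.Date(window_end),
    lookback_years = as.integer(lookback_years),
    seed = as.integer(seed)
  )
  validate_simulation_params(params)
  structure(params, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  if (p$n_persons <= 0) {
    rlang::abort("`n_persons` must be positive.", class = "ascertain_config_error")
  }
  probs <- c(
    prop_true_positive = p$prop_true_positive,
    false_positive_rate = p$false_positive_rate,
    within_person_correlation = p$within_person_correlation,
    death_flag_sensitivity = p$death_flag_sensitivity,
    private_sector_prob = p$private_sector_prob,
    dialysis_record_prob = p$dialysis_record_prob,
    p$death_prob_by_status, p$death_flag_missing_prob_by_status,
    p$hmdc_missing_prob
  )
  if (is.data.frame(p$sensitivity_by_stratum)) {
    probs <- c(probs, p$sensitivity_by_stratum$sensitivity)
  } else {
    probs <- c(probs, sensitivity = p$sensitivity_by_stratum)
  }
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad)) {
    rlang::abort(
      sprintf("Probabilities must lie in [0, 1]; offending value(s): %s.",
              paste(utils::head(names(probs)[bad], 3), collapse = ", ")),
      class = "ascertain_config_error"
    )
  }
  for (nm in c("death_prob_by_status", "death_flag_missing_prob_by_status")) {
    if (!all(c("positive", "negative") %in% names(p[[nm]]))) {
      rlang::abort(sprintf("`%s` needs entries 'positive' and 'negative'.", nm),
                   class = "ascertain_config_error")
    }
  }
  if (p$admissions_per_person$mean <= 0) {
    rlang::abort("`admissions_per_person$mean` must be positive.",
                 class = "ascertain_config_error")
  }
  invisible(p)
}

#' Default stratum-level recording sensitivity
#'
#' Per-record probability that a truly positive person's hospital record is
#' flagged positive, over the full ARIA x age-band x SEIFA grid. The default
#' surface is built from additive logit effects encoding the qualitative
#' gradient seen in audits of Australian administrative data: recording is
#' most reliable in remote and very remote areas and in more disadvantaged
#' areas, and declines for older people and in metropolitan / urban
#' settings. The exact values are configuration, not empirical claims.
#'
#' @param base_sensitivity Sensitivity at the logit intercept.
#' @return Tibble with columns `aria_category`, `age_band`,
#'   `seifa_quintile`, `sensitivity` (75 rows).
#' @export
default_sensitivity_map <- function(base_sensitivity = 0.85) {
  aria_eff <- c(-1.1, -1.4, -0.9, 0.8, 1.6)       # metro..very remote
  age_eff <- c(0.7, 0, -1.4)                      # 0-34, 35-64, 65+
  seifa_eff <- c(0.5, 0.2, -0.3, -0.2, -0.9)      # most..least disadvantaged
  grid <- tidyr::expand_grid(
    aria_category = 1:5,
    age_band = c("0-34", "35-64", "65+"),
    seifa_quintile = 1:5
  )
  grid$sensitivity <- stats::plogis(
    stats::qlogis(base_sensitivity) +
      aria_eff[grid$aria_category] +
      age_eff[match(grid$age_band, c("0-34", "35-64", "65+"))] +
      seifa_eff[grid$seifa_quintile]
  )
  grid
}

# stratum sampling weights shared by the generator and the closed-form
# expectation helpers; positives skew remote, disadvantaged and younger
aria_probs <- function(true_positive) {
  if (true_positive) c(0.20, 0.10, 0.17, 0.18, 0.35)
  else c(0.72, 0.10, 0.11, 0.05, 0.02)
}

seifa_probs <- function(true_positive) {
  if (true_positive) c(0.35, 0.30, 0.20, 0.10, 0.05)
  else c(0.15, 0.20, 0.20, 0.22, 0.23)
}

age_weights <- function(true_positive) {
  ages <- 25:74
  w <- if (true_positive) seq(1.5, 0.2, length.out = 50)
       else seq(0.8, 1.2, length.out = 50)
  stats::setNames(w / sum(w), ages)
}

age_band_probs <- function(true_positive) {
  w <- age_weights(true_positive)
  band <- as.character(age_band(as.integer(names(w)), "summary"))
  tapply(w, band, sum)[c("0-34", "35-64", "65+")]
}

lookup_sensitivity <- function(persons, map) {
  if (!is.data.frame(map)) {
    return(rep(as.numeric(map), nrow(persons)))
  }
  joined <- dplyr::left_join(
    persons, map, by = c("aria_category", "age_band", "seifa_quintile")
  )
  if (anyNA(joined$sensitivity)) {
    rlang::abort("`sensitivity_by_stratum` does not cover every stratum.",
                 class = "ascertain_config_error")
  }
  joined$sensitivity
}

cvd_dx_pool <- function() c("I21", "I25", "I50", "I20", "I10", "I63", "I48")

other_dx_pool <- function() {
  c("J18", "K35", "S72", "E11", "N39", "R07", "M54", "C50", "I21", "I10")
}

rtpois <- function(n, mean) {
  # Poisson truncated at >= 1 via inverse-cdf on the conditional tail
  stats::qpois(stats::runif(n, stats::ppois(0, mean), 1), mean)
}

#' Generate a synthetic linked cohort
#'
#' Draws a full synthetic extract pair (admissions, deaths) plus the
#' ground-truth ledger, according to [simulation_params()]. Output is fully
#' reproducible given the seed, and the extracts follow the
#' [admissions_schema()] / [deaths_schema()] exactly, so they round-trip
#' through the readers and feed straight into [build_cohort()].
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `admissions`, `deaths`, `truth`, and the `params` used.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_persons

  persons <- tibble::tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    true_positive = stats::runif(n) < params$prop_true_positive,
    sex = sample(c("M", "F"), n, replace = TRUE)
  )
  draw_strat <- function(probs_fn, values) {
    out <- integer(n)
    for (tp in c(TRUE, FALSE)) {
      idx <- which(persons$true_positive == tp)
      out[idx] <- sample(values, length(idx), replace = TRUE,
                         prob = probs_fn(tp))
    }
    out
  }
  persons$aria_category <- draw_strat(aria_probs, 1:5)
  persons$seifa_quintile <- draw_strat(seifa_probs, 1:5)
  persons$age_years <- integer(n)
  for (tp in c(TRUE, FALSE)) {
    idx <- which(persons$true_positive == tp)
    w <- age_weights(tp)
    persons$age_years[idx] <- sample(as.integer(names(w)), length(idx),
                                     replace = TRUE, prob = w)
  }
  persons$region <- dplyr::if_else(persons$aria_category == 1L,
                                   "METRO", "NON_METRO")
  persons$age_band <- as.character(age_band(persons$age_years, "summary"))
  persons$sensitivity <- dplyr::if_else(
    persons$true_positive,
    lookup_sensitivity(persons, params$sensitivity_by_stratum),
    params$false_positive_rate
  )

  # index admission: public CVD separation inside the window
  window_days <- as.integer(params$window_end - params$window_start)
  index_sep <- params$window_start +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L
  index_los <- sample(0:14, n, replace = TRUE,
                      prob = c(0.15, rep(0.85 / 14, 14)))
  index <- persons |>
    dplyr::mutate(
      separation_date = index_sep,
      admission_date = index_sep - index_los,
      principal_dx = sample(cvd_dx_pool(), n, replace = TRUE),
      icd_version = "ICD10AM",
      sector = "PUBLIC",
      same_day = index_los == 0L,
      is_index = TRUE
    )

  # lookback admissions: any cause, public and private, 20 years back
  persons$n_lookback <- rtpois(n, params$admissions_per_person$mean)
  lb <- persons[rep(seq_len(n), persons$n_lookback),
                c("person_id", "true_positive", "sex", "aria_category",
                  "seifa_quintile", "region", "sensitivity")]
  m <- nrow(lb)
  index_adm <- rep(index$admission_date, persons$n_lookback)
  max_offset <- as.integer(floor(365.25 * params$lookback_years)) - 30L
  offsets <- sample.int(max_offset, m, replace = TRUE)
  lb_los <- sample(0:10, m, replace = TRUE,
                   prob = c(0.35, rep(0.65 / 10, 10)))
  dialysis <- stats::runif(m) < params$dialysis_record_prob
  lb <- lb |>
    dplyr::mutate(
      admission_date = index_adm - offsets,
      age_years = pmax(0L, rep(persons$age_years, persons$n_lookback) -
                         as.integer(floor(offsets / 365.25))),
      same_day = dialysis | lb_los == 0L,
      separation_date = .data$admission_date +
        dplyr::if_else(.data$same_day, 0L, lb_los),
      sector = dplyr::if_else(
        stats::runif(m) < params$private_sector_prob, "PRIVATE", "PUBLIC"),
      icd_version = dplyr::if_else(.data$admission_date < as.Date("1999-07-01"),
                                   "ICD9CM", "ICD10AM"),
      principal_dx = dplyr::if_else(
        dialysis,
        dplyr::if_else(.data$icd_version == "ICD9CM", "V56", "Z49"),
        sample(other_dx_pool(), m, replace = TRUE)),
      is_index = FALSE
    )

  cols <- c("person_id", "admission_date", "separation_date", "principal_dx",
            "icd_version", "sector", "same_day", "sex", "age_years",
            "region", "seifa_quintile", "aria_category", "is_index",
            "true_positive", "sensitivity")
  recs <- dplyr::bind_rows(lb[, cols], index[, cols]) |>
    dplyr::arrange(.data$person_id, .data$admission_date, !.data$is_index)

  # recorded-flag chain: first record Bernoulli(sensitivity or fp), later
  # records copy the previous recorded flag w.p. rho, else redraw
  nr <- nrow(recs)
  draw <- stats::runif(nr) < recs$sensitivity
  copy <- stats::runif(nr) < params$within_person_correlation
  recs <- recs |>
    dplyr::mutate(.rown = dplyr::row_number()) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(
      .copy = copy[.data$.rown] & dplyr::row_number() > 1L,
      .src = cummax(dplyr::if_else(.data$.copy, 0L, .data$.rown))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(flag_positive = draw[.data$.src])

  # missingness of the hospital flag (private-sector records only)
  mp <- params$hmdc_missing_prob
  miss_prob <- if (length(mp) > 1 && !is.null(names(mp))) {
    unname(mp[recs$region])
  } else {
    rep(as.numeric(mp[1]), nr)
  }
  recs$flag_missing <- recs$sector == "PRIVATE" &
    stats::runif(nr) < miss_prob

  # era-specific coding; missing flags are representable only as an absent
  # four-category code
  legacy <- recs$admission_date < as.Date("2000-01-01") & !recs$flag_missing
  pos_code <- sample(1:3, nr, replace = TRUE, prob = c(0.9, 0.05, 0.05))
  recs <- recs |>
    dplyr::mutate(
      status_era = dplyr::if_else(legacy, "legacy_binary", "four_category"),
      status_code = dplyr::case_when(
        .data$flag_missing ~ NA_integer_,
        legacy & .data$flag_positive ~ 2L,
        legacy ~ 1L,
        .data$flag_positive ~ pos_code,
        .default = 4L
      )
    )

  admissions <- recs[, names(admissions_schema())]

  # deaths: status-dependent probability, informatively missing flags
  dp <- params$death_prob_by_status
  died <- stats::runif(n) <
    dplyr::if_else(persons$true_positive, dp[["positive"]], dp[["negative"]])
  gap <- as.integer(params$window_end - index_sep)
  death_date <- index_sep + floor(stats::runif(n) * (gap + 1L))
  mp_d <- params$death_flag_missing_prob_by_status
  death_missing <- stats::runif(n) <
    dplyr::if_else(persons$true_positive, mp_d[["positive"]], mp_d[["negative"]])
  death_pos <- stats::runif(n) <
    dplyr::if_else(persons$true_positive, params$death_flag_sensitivity,
                   params$false_positive_rate)
  death_code <- dplyr::case_when(
    death_missing ~ NA_integer_,
    death_pos ~ sample(1:3, n, replace = TRUE, prob = c(0.9, 0.05, 0.05)),
    .default = 4L
  )
  deaths <- tibble::tibble(
    person_id = persons$person_id[died],
    death_date = death_date[died],
    status_code = death_code[died],
    status_era = "four_category"
  )

  truth <- persons |>
    dplyr::mutate(
      died = died,
      death_flag_missing = dplyr::if_else(died, death_missing, NA),
      index_separation = index_sep
    ) |>
    dplyr::select("person_id", "true_positive", "sex", "age_years",
                  "age_band", "region", "aria_category", "seifa_quintile",
                  "sensitivity", "n_lookback", "died", "death_flag_missing",
                  "index_separation")

  structure(list(admissions = admissions, deaths = deaths, truth = truth,
                 params = params),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `admissions.csv` and `deaths.csv` in the canonical schemas, plus
#' `truth.csv` (ground-truth ledger) and `params.json` (parameter echo), to
#' `dir`.
#'
#' @param params A [simulation_params()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the `synthetic_cohort` that was written.
#' @export
simulate_to_csv <- function(params, dir) {
  sim <- simulate_cohort(params)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_admissions(sim$admissions, file.path(dir, "admissions.csv"))
  write_deaths(sim$deaths, file.path(dir, "deaths.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  echo <- sim$params
  echo$sensitivity_by_stratum <- NULL
  jsonlite::write_json(
    c(lapply(unclass(echo), function(x) if (inherits(x, "Date")) as.character(x) else x),
      list(sensitivity_by_stratum = if (is.data.frame(params$sensitivity_by_stratum))
        "stratum map (75 rows)" else params$sensitivity_by_stratum)),
    file.path(dir, "params.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(sim)
}
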