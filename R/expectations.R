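#' Probability of ever being flagged positive over a record chain
#'
#' Closed-form probability that at least one of `k` chained records carries
#' a positive flag, under the generative rule of [simulate_cohort()]: the
#' first record is Bernoulli(`s`) and each subsequent record copies the
#' previous recorded flag with probability `rho`, otherwise is re-drawn
#' Bernoulli(`s`).
#'
#' The all-negative chain requires a negative first draw (probability
#' `1 - s`) and each later record either copying the standing negative
#' (`rho`) or re-drawing negative (`(1 - rho)(1 - s)`), giving
#' `P(ever) = 1 - (1 - s) * (rho + (1 - rho)(1 - s))^(k - 1)`. With
#' `rho = 0` this reduces to the independent-records form `1 - (1 - s)^k`.
#'
#' @param s Per-record flag sensitivity, in \[0, 1\].
#' @param k Number of records (>= 1); vectorised.
#' @param rho Within-person copy probability, in \[0, 1\].
#' @return Probability vector, same length as `k`.
#' @examples
#' expected_ever_sensitivity(0.5, 3, 0)    # 0.875
#' expected_ever_sensitivity(0.7, 4, 0.5)
#' @export
expected_ever_sensitivity <- function(s, k, rho = 0) {
  stopifnot(length(s) == 1, length(rho) == 1,
            s >= 0, s <= 1, rho >= 0, rho <= 1)
  k <- as.integer(k)
  if (any(k < 1)) {
    rlang::abort("`k` must be >= 1.", class = "ascertain_config_error")
  }
  1 - (1 - s) * (rho + (1 - rho) * (1 - s))^(k - 1)
}

tpois_pmf <- function(lambda, kmax = NULL) {
  if (is.null(kmax)) kmax <- max(10L, stats::qpois(1 - 1e-10, lambda))
  k <- seq_len(kmax)
  p <- stats::dpois(k, lambda) / (1 - stats::dpois(0, lambda))
  p / sum(p)
}

# stratum-averaged chain quantities for truly positive persons:
# E[s] (index-record marginal) and E[P(ever positive)] over the joint
# stratum distribution and the truncated-Poisson lookback count
stratum_expectations <- function(params) {
  map <- params$sensitivity_by_stratum
  bands <- c("0-34", "35-64", "65+")
  if (is.data.frame(map)) {
    strata <- map
    strata$weight <- aria_probs(TRUE)[strata$aria_category] *
      seifa_probs(TRUE)[strata$seifa_quintile] *
      as.numeric(age_band_probs(TRUE)[strata$age_band])
  } else {
    strata <- tibble::tibble(sensitivity = as.numeric(map), weight = 1)
  }
  strata$weight <- strata$weight / sum(strata$weight)
  pk <- tpois_pmf(params$admissions_per_person$mean)
  k_total <- seq_along(pk) + 1L  # lookback + index record
  rho <- params$within_person_correlation
  ever_by_stratum <- vapply(strata$sensitivity, function(s) {
    sum(pk * expected_ever_sensitivity(s, k_total, rho))
  }, numeric(1))
  fp_ever <- sum(pk * expected_ever_sensitivity(
    params$false_positive_rate, k_total, rho))
  list(
    index_sens = sum(strata$weight * strata$sensitivity),
    ever_sens = sum(strata$weight * ever_by_stratum),
    fp_index = params$false_positive_rate,
    fp_ever = fp_ever
  )
}

#' Closed-form expectations for a simulated cohort
#'
#' Expected per-person identification rates under the generative model of
#' [simulate_cohort()], by direct numerical expectation over the stratum
#' distribution and the truncated-Poisson record count: the index-rule rate,
#' the hospital ever rate, the combined (hospital-or-death) rates, and the
#' implied under-ascertainment of the index count relative to the combined
#' ever count. Record missingness and excluded dialysis records are ignored
#' (both are rare under the defaults and second-order for these rates).
#'
#' @param params A [simulation_params()] object.
#' @return A list with `index_rate`, `ever_hmdc_rate`, `index_death_rate`,
#'   `ever_combined_rate`, and `underestimate_pct` (full precision).
#' @export
expected_counts <- function(params) {
  se <- stratum_expectations(params)
  pi <- params$prop_true_positive
  dp <- params$death_prob_by_status
  mp <- params$death_flag_missing_prob_by_status
  # probability of a positive stated death flag
  q_pos <- dp[["positive"]] * (1 - mp[["positive"]]) *
    params$death_flag_sensitivity
  q_neg <- dp[["negative"]] * (1 - mp[["negative"]]) *
    params$false_positive_rate
  index_rate <- pi * se$index_sens + (1 - pi) * se$fp_index
  ever_hmdc <- pi * se$ever_sens + (1 - pi) * se$fp_ever
  index_death <- pi * (1 - (1 - se$index_sens) * (1 - q_pos)) +
    (1 - pi) * (1 - (1 - se$fp_index) * (1 - q_neg))
  ever_combined <- pi * (1 - (1 - se$ever_sens) * (1 - q_pos)) +
    (1 - pi) * (1 - (1 - se$fp_ever) * (1 - q_neg))
  list(
    index_rate = index_rate,
    ever_hmdc_rate = ever_hmdc,
    index_death_rate = index_death,
    ever_combined_rate = ever_combined,
    underestimate_pct = (1 - index_rate / ever_combined) * 100
  )
}

#' Expected informative-missingness relative risk
#'
#' The expected value of the cross-tabulation relative risk — probability of
#' being hospital-identified among deaths with a missing death flag versus
#' deaths with a stated flag — under the generative model, computed from the
#' configured death and missingness probabilities and the stratum-averaged
#' hospital ever-sensitivity. This is the estimand the pipeline's
#' [death_cross_tab()] recovers; it tracks the configured missingness ratio
#' `death_flag_missing_prob(positive) / death_flag_missing_prob(negative)`
#' closely when prevalence and missingness are low.
#'
#' @param params A [simulation_params()] object.
#' @return A list with `expected_rr`, `configured_ratio`, and the deceased
#'   composition used (`prev_deceased`).
#' @export
expected_missingness_rr <- function(params) {
  se <- stratum_expectations(params)
  pi <- params$prop_true_positive
  dp <- params$death_prob_by_status
  mp <- params$death_flag_missing_prob_by_status
  pi_d <- pi * dp[["positive"]] /
    (pi * dp[["positive"]] + (1 - pi) * dp[["negative"]])
  h_pos <- se$ever_sens
  h_neg <- se$fp_ever
  m_p <- mp[["positive"]]
  m_n <- mp[["negative"]]
  p_missing <- pi_d * m_p + (1 - pi_d) * m_n
  p_stated <- pi_d * (1 - m_p) + (1 - pi_d) * (1 - m_n)
  rate_missing <- (pi_d * m_p * h_pos + (1 - pi_d) * m_n * h_neg) / p_missing
  rate_stated <- (pi_d * (1 - m_p) * h_pos +
                    (1 - pi_d) * (1 - m_n) * h_neg) / p_stated
  list(
    expected_rr = rate_missing / rate_stated,
    configured_ratio = m_p / m_n,
    prev_deceased = pi_d
  )
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline — simulate, build the cohort, classify, tabulate —
#' over `n_replicates` seeded replicates and compares the recovered
#' quantities against their configured / closed-form expectations:
#'
#' * the under-ascertainment of the index count relative to the combined
#'   ever count, against [expected_counts()];
#' * the death-record informative-missingness relative risk, against both
#'   the configured missingness ratio and [expected_missingness_rr()].
#'
#' The Monte-Carlo standard error reported is, for a single replicate, the
#' estimator's own sampling SE (Katz log-scale SE for the relative risk,
#' binomial delta SE for the percentage); across replicates, the standard
#' error of the replicate mean.
#'
#' @param params A [simulation_params()] object; replicate `r` runs at seed
#'   `params$seed + r - 1`.
#' @param n_replicates Number of replicates (>= 1).
#' @return A tibble of class `recovery_report` with columns `quantity`,
#'   `configured`, `expected`, `estimate`, `mc_se`, `n_replicates`, and a
#'   `replicates` attribute holding the per-replicate estimates.
#' @export
recovery_experiment <- function(params = simulation_params(),
                                n_replicates = 1) {
  stopifnot(inherits(params, "simulation_params"))
  if (n_replicates < 1) {
    rlang::abort("`n_replicates` must be at least 1.",
                 class = "ascertain_config_error")
  }
  spec <- cohort_spec(window_start = params$window_start,
                      window_end = params$window_end,
                      lookback_years = params$lookback_years)
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    p <- params
    p$seed <- params$seed + r - 1L
    sim <- simulate_cohort(p)
    cohort <- build_cohort(sim$admissions, sim$deaths, spec)
    res <- classify_status(cohort)
    counts <- method_counts(res)
    u <- underestimation_pct(counts[["index"]], counts[["ever_death"]],
                             digits = NULL)
    p_hat <- counts[["index"]] / counts[["ever_death"]]
    u_se <- 100 * sqrt(p_hat * (1 - p_hat) / counts[["ever_death"]])
    ct <- death_cross_tab(res)
    if (is.null(ct$missingness_rr)) {
      rr <- rr_se <- NA_real_
    } else {
      est <- ct$missingness_rr
      log_se <- sqrt(1 / est$a - 1 / est$n1 + 1 / est$b - 1 / est$n2)
      rr <- est$estimate
      rr_se <- rr * log_se
    }
    tibble::tibble(replicate = r, seed = p$seed,
                   underestimate_pct = u, underestimate_se = u_se,
                   missingness_rr = rr, missingness_rr_se = rr_se)
  }) |> purrr::list_rbind()

  exp_counts <- expected_counts(params)
  exp_rr <- expected_missingness_rr(params)
  summarise_q <- function(est, se1) {
    if (n_replicates == 1) c(mean(est), se1[1])
    else c(mean(est), stats::sd(est) / sqrt(n_replicates))
  }
  u_sum <- summarise_q(reps$underestimate_pct, reps$underestimate_se)
  rr_sum <- summarise_q(reps$missingness_rr, reps$missingness_rr_se)
  out <- tibble::tibble(
    quantity = c("underestimate_pct", "missingness_rr"),
    configured = c(NA_real_, exp_rr$configured_ratio),
    expected = c(exp_counts$underestimate_pct, exp_rr$expected_rr),
    estimate = c(u_sum[1], rr_sum[1]),
    mc_se = c(u_sum[2], rr_sum[2]),
    n_replicates = n_replicates
  )
  out <- tibble::new_tibble(out, class = "recovery_report")
  attr(out, "replicates") <- reps
  out
}
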