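test_that("the generator is deterministic under a fixed seed", {
  p <- small_params(n = 100, seed = 12)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_to_csv(p, d1)
  simulate_to_csv(p, d2)
  for (f in c("admissions.csv", "deaths.csv", "truth.csv")) {
    expect_identical(readr::read_file(file.path(d1, f)),
                     readr::read_file(file.path(d2, f)), label = f)
  }

  other <- simulate_cohort(small_params(n = 100, seed = 13))
  expect_false(identical(a$admissions, other$admissions))
})

test_that("simulated extracts satisfy the schema invariants", {
  sim <- simulate_cohort(small_params(n = 200, seed = 3))
  adm <- validate_admissions(sim$admissions)
  expect_equal(nrow(validation_report(adm)), 0)
  dth <- validate_deaths(sim$deaths)
  expect_equal(nrow(validation_report(dth)), 0)
  # legacy coding appears before 2000 and four-category after
  pre <- sim$admissions[sim$admissions$admission_date < as.Date("2000-01-01") &
                          !is.na(sim$admissions$status_code), ]
  expect_true(all(pre$status_era == "legacy_binary"))
  post <- sim$admissions[sim$admissions$admission_date >= as.Date("2000-01-01"), ]
  expect_true(all(post$status_era == "four_category"))
})

test_that("perfect recording collapses all four rules to the truth", {
  sim <- simulate_cohort(small_params(
    n = 250, seed = 19, sensitivity_by_stratum = 1,
    false_positive_rate = 0, death_flag_sensitivity = 1,
    death_flag_missing_prob_by_status = c(positive = 0, negative = 0)
  ))
  res <- classify_status(build_cohort(sim$admissions, sim$deaths))
  counts <- method_counts(res)
  n_true <- sum(sim$truth$true_positive)
  expect_equal(unname(counts), rep(n_true, 4))
  tab <- tabulate_ascertainment(res)
  expect_true(all(tab$underestimate_pct == 0))
})

test_that("with zero hospital sensitivity positives surface only through deaths", {
  sim <- simulate_cohort(small_params(
    n = 250, seed = 23, sensitivity_by_stratum = 0,
    false_positive_rate = 0, death_flag_sensitivity = 1,
    death_flag_missing_prob_by_status = c(positive = 0, negative = 0)
  ))
  res <- classify_status(build_cohort(sim$admissions, sim$deaths))
  tab <- tabulate_ascertainment(res)
  expect_true(all(tab$morbidity_alone == 0))
  died_pos <- sum(sim$truth$true_positive & sim$truth$died)
  expect_equal(unname(tab$combined), rep(died_pos, 3))
})

test_that("chain ever-probability matches its closed form and a brute-force oracle", {
  expect_equal(expected_ever_sensitivity(0.5, 1, 0), 0.5)
  expect_equal(expected_ever_sensitivity(0.5, 3, 0), 0.875)
  expect_equal(expected_ever_sensitivity(0.3, 5, 1), 0.3)  # full copying

  # exhaustive enumeration over draw/copy outcomes for s=0.7, k=4, rho=0.5
  brute_ever <- function(s, k, rho) {
    total <- 0
    enumerate <- function(i, chain, prob) {
      if (i > k) {
        if (any(chain)) total <<- total + prob
        return(invisible())
      }
      if (i == 1) {
        enumerate(2, TRUE, s)
        enumerate(2, FALSE, 1 - s)
      } else {
        enumerate(i + 1, c(chain, chain[i - 1]), prob * rho)
        enumerate(i + 1, c(chain, TRUE), prob * (1 - rho) * s)
        enumerate(i + 1, c(chain, FALSE), prob * (1 - rho) * (1 - s))
      }
    }
    enumerate(1, logical(), 1)
    total
  }
  expect_equal(expected_ever_sensitivity(0.7, 4, 0.5), brute_ever(0.7, 4, 0.5),
               tolerance = 1e-12)
  expect_equal(expected_ever_sensitivity(0.4, 3, 0.8), brute_ever(0.4, 3, 0.8),
               tolerance = 1e-12)
  expect_error(expected_ever_sensitivity(0.5, 0, 0),
               class = "ascertain_config_error")
})

test_that("with independent records the ever rate converges to 1-(1-s)^k", {
  s <- 0.3
  sim <- simulate_cohort(small_params(
    n = 15000, seed = 29, sensitivity_by_stratum = s,
    within_person_correlation = 0, false_positive_rate = 0,
    dialysis_record_prob = 0,
    death_prob_by_status = c(positive = 0, negative = 0)
  ))
  res <- classify_status(build_cohort(sim$admissions, sim$deaths))
  truth <- sim$truth
  pos <- truth[truth$true_positive, ]
  expected_rate <- mean(expected_ever_sensitivity(s, pos$n_lookback + 1, 0))
  observed_rate <- mean(res$ever_pos[match(pos$person_id, res$person_id)])
  se <- sqrt(expected_rate * (1 - expected_rate) / nrow(pos))
  expect_lt(abs(observed_rate - expected_rate), 4 * se)
})

test_that("raising sensitivity does not raise estimated under-ascertainment", {
  u_at <- function(s) {
    sim <- simulate_cohort(small_params(n = 4000, seed = 37,
                                        sensitivity_by_stratum = s))
    res <- classify_status(build_cohort(sim$admissions, sim$deaths))
    counts <- method_counts(res)
    underestimation_pct(counts[["index"]], counts[["ever_death"]],
                        digits = NULL)
  }
  u <- vapply(c(0.3, 0.5, 0.7, 0.9), u_at, numeric(1))
  expect_true(all(diff(u) < 1))  # non-increasing up to Monte-Carlo jitter
  expect_gt(u[1], u[4])
})

test_that("summaries are stable across seeds", {
  u <- vapply(1:5, function(seed) {
    sim <- simulate_cohort(small_params(n = 2000, seed = seed))
    res <- classify_status(build_cohort(sim$admissions, sim$deaths))
    counts <- method_counts(res)
    underestimation_pct(counts[["index"]], counts[["ever_death"]],
                        digits = NULL)
  }, numeric(1))
  # all seeds draw from the same sampling distribution
  expect_lt(diff(range(u)), 15)
  expect_gt(mean(u), 5)
})

test_that("invalid parameters are rejected with a config error", {
  expect_error(simulation_params(prop_true_positive = 1.5),
               class = "ascertain_config_error")
  expect_error(simulation_params(death_prob_by_status = c(positive = 0.5)),
               class = "ascertain_config_error")
  expect_error(simulation_params(n_persons = 0),
               class = "ascertain_config_error")
  incomplete_map <- default_sensitivity_map()[1:10, ]
  expect_error(
    simulate_cohort(small_params(n = 50,
                                 sensitivity_by_stratum = incomplete_map)),
    class = "ascertain_config_error"
  )
})

test_that("the recovery experiment reports estimates against expectations", {
  expect_error(recovery_experiment(small_params(n = 50), n_replicates = 0),
               class = "ascertain_config_error")
  rep <- recovery_experiment(small_params(n = 1500, seed = 61),
                             n_replicates = 2)
  expect_setequal(rep$quantity, c("underestimate_pct", "missingness_rr"))
  expect_true(all(rep$mc_se > 0, na.rm = TRUE))
  reps <- attr(rep, "replicates")
  expect_equal(reps$seed, c(61L, 62L))
  expect_equal(rep$configured[rep$quantity == "missingness_rr"], 1.9)
})
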