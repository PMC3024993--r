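test_that("the most recent qualifying separation becomes the index record", {
  adm <- dplyr::bind_rows(
    make_admission("A", "2001-03-01", "2001-03-05"),
    make_admission("A", "2004-07-01", "2004-07-08"),
    make_admission("B", "2003-01-01", "2003-01-02", sector = "PRIVATE"),
    make_admission("C", "2003-01-01", "2003-01-02", dx = "J18"),
    make_admission("D", "2003-01-01", "2003-01-02", age = 80),
    make_admission("E", "1999-06-01", "1999-06-02")   # outside window
  )
  idx <- select_index(adm, cohort_spec())
  expect_equal(idx$person_id, "A")
  expect_equal(idx$separation_date, as.Date("2004-07-08"))
})

test_that("index ties break by latest admission date, then stable input order", {
  adm <- dplyr::bind_rows(
    make_admission("A", "2004-07-01", "2004-07-08", dx = "I21"),
    make_admission("A", "2004-07-05", "2004-07-08", dx = "I50"),
    make_admission("B", "2004-07-05", "2004-07-08", dx = "I21"),
    make_admission("B", "2004-07-05", "2004-07-08", dx = "I50")
  )
  idx <- select_index(adm, cohort_spec())
  expect_equal(idx$principal_dx[idx$person_id == "A"], "I50")
  expect_equal(idx$principal_dx[idx$person_id == "B"], "I21")
})

test_that("diagnosis matching is prefix-based on the normalised code", {
  adm <- dplyr::bind_rows(
    make_admission("A", "2003-01-01", "2003-01-02", dx = "I25.1"),
    make_admission("B", "2003-01-01", "2003-01-02", dx = "i48"),
    make_admission("C", "2003-01-01", "2003-01-02", dx = "X95")
  )
  idx <- select_index(adm, cohort_spec())
  expect_setequal(idx$person_id, c("A", "B"))
})

test_that("lookback keeps in-window admissions and drops same-day dialysis", {
  adm <- dplyr::bind_rows(
    make_admission("A", "2004-06-01", "2004-06-05"),                    # index
    make_admission("A", "2000-02-01", "2000-02-01", dx = "Z49.1"),      # same-day dialysis
    make_admission("A", "2000-03-01", "2000-03-03", dx = "Z49.1"),      # overnight: retained
    make_admission("A", "1990-01-01", "1990-01-01", dx = "V56",
                   era = "legacy_binary", code = 1, icd = "ICD9CM"),    # same-day dialysis, old coding
    make_admission("A", "1983-01-01", "1983-01-02", dx = "J18",
                   era = "legacy_binary", code = 1, icd = "ICD9CM"),    # 21 years before index
    make_admission("A", "1995-05-05", "1995-05-06", dx = "K35",
                   era = "legacy_binary", code = 1, icd = "ICD9CM",
                   sector = "PRIVATE")
  )
  idx <- select_index(adm, cohort_spec())
  lb <- build_lookback(adm, idx, cohort_spec())
  expect_setequal(as.character(lb$admission_date),
                  c("1995-05-05", "2000-03-01", "2004-06-01"))
  expect_equal(sum(lb$is_index), 1)
  # chronological within person
  expect_equal(lb$admission_date, sort(lb$admission_date))
})

test_that("the lookback window is half-open on the left and closed at the index date", {
  index_adm <- as.Date("2004-06-01")
  boundary <- index_adm - lubridate::years(20)
  adm <- dplyr::bind_rows(
    make_admission("A", index_adm, "2004-06-05"),
    make_admission("A", boundary, boundary + 1, dx = "J18"),       # exactly 20y: out
    make_admission("A", boundary + 1, boundary + 2, dx = "J18"),   # just inside
    make_admission("A", "2004-06-01", "2004-06-01", dx = "J18")    # index day
  )
  idx <- select_index(adm, cohort_spec())
  lb <- build_lookback(adm, idx, cohort_spec())
  expect_equal(nrow(lb), 3)
  expect_false(boundary %in% lb$admission_date)
})

test_that("deaths attach only on or after the index separation and inside the window", {
  adm <- dplyr::bind_rows(
    make_admission("A", "2003-05-01", "2003-05-06"),
    make_admission("B", "2003-05-01", "2003-05-06"),
    make_admission("C", "2003-05-01", "2003-05-06")
  )
  deaths <- dplyr::bind_rows(
    make_death("A", "2005-02-01", 1),
    make_death("B", "2003-04-30"),   # predates index separation
    make_death("C", "2006-03-01"),   # after window end
    make_death("Z", "2004-01-01")    # no index admission: ignored
  )
  idx <- select_index(adm, cohort_spec())
  att <- attach_deaths(idx, deaths, cohort_spec())
  expect_equal(att$deaths$person_id, "A")
  expect_setequal(att$anomalies$person_id, c("B", "C"))
  expect_equal(
    att$anomalies$reason[att$anomalies$person_id == "B"],
    "death_predates_index_separation"
  )
  expect_false("Z" %in% c(att$deaths$person_id, att$anomalies$person_id))
})

test_that("every cohort member's history contains its index record exactly once", {
  sim <- simulate_cohort(small_params(n = 300, seed = 5))
  cohort <- build_cohort(sim$admissions, sim$deaths)
  per_person <- tapply(cohort$history$is_index, cohort$history$person_id, sum)
  expect_true(all(per_person == 1))
  expect_equal(sort(unique(cohort$history$person_id)),
               sort(cohort$index$person_id))
})

test_that("cohort size is monotone non-increasing as eligibility narrows", {
  sim <- simulate_cohort(small_params(n = 300, seed = 8))
  n_full <- nrow(build_cohort(sim$admissions, spec = cohort_spec())$index)
  n_dx <- nrow(build_cohort(sim$admissions,
                            spec = cohort_spec(dx_prefixes = "I2"))$index)
  n_win <- nrow(build_cohort(
    sim$admissions,
    spec = cohort_spec(window_start = "2002-01-01",
                       window_end = "2003-12-31"))$index)
  expect_lte(n_dx, n_full)
  expect_lte(n_win, n_full)
  expect_gt(n_full, 0)
})

test_that("without dialysis records the exclusion is a no-op", {
  sim <- simulate_cohort(small_params(n = 200, seed = 9,
                                      dialysis_record_prob = 0))
  with_excl <- build_cohort(sim$admissions, spec = cohort_spec())
  no_excl <- build_cohort(sim$admissions,
                          spec = cohort_spec(dialysis_codes = "XXX"))
  expect_equal(with_excl$history, no_excl$history)
})

test_that("cohort definitions round-trip through JSON", {
  spec <- cohort_spec(age_min = 30, dx_prefixes = c("I2", "I5"),
                      lookback_years = 10)
  path <- withr::local_tempfile(fileext = ".json")
  cohort_spec_to_json(spec, path)
  back <- cohort_spec_from_json(path)
  expect_equal(back, spec)
  expect_error(cohort_spec(window_start = "2005-01-01",
                           window_end = "2000-01-01"))
  expect_error(cohort_spec(lookback_years = 0))
})
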