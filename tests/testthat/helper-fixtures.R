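# in-code fixture builders: single admission / death rows in the canonical
# schemas, and a hand-assembled linked cohort for classification tests

make_admission <- function(person_id, admission, separation = admission,
                           dx = "I21", sector = "PUBLIC", code = 4L,
                           era = "four_category", sex = "M", age = 50L,
                           region = "METRO", seifa = 3L, aria = 1L,
                           icd = "ICD10AM") {
  admission <- as.Date(admission)
  separation <- as.Date(separation)
  tibble::tibble(
    person_id = person_id, admission_date = admission,
    separation_date = separation, principal_dx = dx, icd_version = icd,
    sector = sector, same_day = admission == separation,
    status_code = as.integer(code), status_era = era, sex = sex,
    age_years = as.integer(age), region = region,
    seifa_quintile = as.integer(seifa), aria_category = as.integer(aria)
  )
}

make_death <- function(person_id, date, code = 4L, era = "four_category") {
  tibble::tibble(person_id = person_id, death_date = as.Date(date),
                 status_code = as.integer(code), status_era = era)
}

# one person's history as a cohort: index flag + lookback flags given as
# status codes (NA = absent), optional death code (NA = absent flag)
hand_cohort <- function(index_code, lookback_codes = integer(),
                        death_code = NULL, lookback_sector = "PUBLIC",
                        person_id = "P1") {
  adm <- make_admission(person_id, "2004-06-01", "2004-06-05",
                        code = index_code)
  if (length(lookback_codes) > 0) {
    dates <- as.Date("2004-06-01") - seq_along(lookback_codes) * 100
    lb <- purrr::map2(lookback_codes, dates, function(code, d) {
      make_admission(person_id, d, d + 1, dx = "J18", code = code,
                     sector = lookback_sector)
    }) |> purrr::list_rbind()
    adm <- dplyr::bind_rows(lb, adm)
  }
  deaths <- NULL
  if (!is.null(death_code)) {
    deaths <- make_death(person_id, "2005-01-01", code = death_code)
  }
  build_cohort(adm, deaths, cohort_spec())
}

# quick small synthetic parameter set for pipeline-level tests
small_params <- function(n = 400, seed = 1, ...) {
  simulation_params(n_persons = n, seed = seed, ...)
}
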