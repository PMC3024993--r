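#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for report output, as opposed to the
#' IEC banker's rounding of [round()]. Internal computations keep full
#' precision; rounding happens only at the reporting surface.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Under-ascertainment (shortfall) percentage
#'
#' The shortfall of an observed single-source count relative to a revised
#' linked-records estimate: `|observed / revised - 1| * 100`. Reported by
#' convention as a positive magnitude.
#'
#' @param observed Observed count (e.g. cases identified in one source).
#' @param revised Revised count after combining linked sources;
#'   `revised >= observed > 0` is expected.
#' @param digits Decimal places for half-up rounding; `NULL` for full
#'   precision.
#' @return Numeric vector of percentages.
#' @examples
#' underestimation_pct(714, 975)   # 26.8
#' underestimation_pct(3060, 3696) # 17.2
#' @export
underestimation_pct <- function(observed, revised, digits = 1) {
  stopifnot(is.numeric(observed), is.numeric(revised))
  if (any(revised <= 0)) {
    rlang::abort("`revised` must be positive.", class = "ascertain_undefined")
  }
  if (any(observed < 0 | observed > revised)) {
    rlang::abort("Expected 0 <= observed <= revised.",
                 class = "ascertain_undefined")
  }
  out <- abs(observed / revised - 1) * 100
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Excess (relative increase) percentage
#'
#' The relative increase over a baseline count when additional cases are
#' identified: `added / baseline * 100`, equivalently
#' `(revised / baseline - 1) * 100` with `revised = baseline + added`.
#'
#' @param baseline Baseline count (> 0).
#' @param added Additional cases identified (>= 0).
#' @param digits Decimal places for half-up rounding; `NULL` for full
#'   precision.
#' @return Numeric vector of percentages.
#' @examples
#' excess_pct(3060, 83)  # 2.7
#' excess_pct(3060, 636) # 20.8
#' @export
excess_pct <- function(baseline, added, digits = 1) {
  stopifnot(is.numeric(baseline), is.numeric(added))
  if (any(baseline <= 0)) {
    rlang::abort("`baseline` must be positive.", class = "ascertain_undefined")
  }
  if (any(added < 0)) {
    rlang::abort("`added` must be non-negative.", class = "ascertain_undefined")
  }
  out <- added / baseline * 100
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

new_ratio_estimate <- function(df) {
  tibble::new_tibble(df, class = "ratio_estimate")
}

#' Wilson score interval for a binomial proportion
#'
#' Computes the Wilson score interval for `k` successes in `n` trials. With
#' `complement = TRUE` the estimate and interval are returned on the
#' complement percentage scale `(1 - p) * 100`, the form used to report
#' under-ascertainment (the share of linked-record cases missed by a single
#' source).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param conf_level Confidence level, default 0.95.
#' @param complement Report `(1 - p) * 100` instead of `p`?
#' @return A one-row `ratio_estimate` tibble with columns `estimate`,
#'   `conf_low`, `conf_high`, `conf_level`, `method`, `k`, `n`.
#' @examples
#' wilson_interval(714, 975, complement = TRUE)  # 26.8 (24.1, 29.6)
#' @export
wilson_interval <- function(k, n, conf_level = 0.95, complement = FALSE) {
  stopifnot(length(k) == 1, length(n) == 1)
  if (n <= 0) {
    rlang::abort("`n` must be positive.", class = "ascertain_undefined")
  }
  if (k < 0 || k > n) {
    rlang::abort("Expected 0 <= k <= n.", class = "ascertain_undefined")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  lo <- centre - half
  hi <- centre + half
  if (complement) {
    est <- (1 - p) * 100
    bounds <- c((1 - hi) * 100, (1 - lo) * 100)
  } else {
    est <- p
    bounds <- c(lo, hi)
  }
  new_ratio_estimate(tibble::tibble(
    estimate = est, conf_low = bounds[1], conf_high = bounds[2],
    conf_level = conf_level,
    method = if (complement) "wilson_complement_pct" else "wilson_proportion",
    k = as.integer(k), n = as.integer(n)
  ))
}

#' Relative risk with Katz log-normal confidence interval
#'
#' Risk ratio between two groups, `(a/n1) / (b/n2)`, with the Katz
#' confidence interval `exp(log RR +/- z * sqrt(1/a - 1/n1 + 1/b - 1/n2))`.
#' When either numerator is zero the point estimate is returned with the
#' interval flagged undefined (`NA` bounds, with a warning).
#'
#' @param a,n1 Events and total in the exposed group.
#' @param b,n2 Events and total in the reference group.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row `ratio_estimate` tibble with columns `estimate`,
#'   `conf_low`, `conf_high`, `conf_level`, `method`, `a`, `n1`, `b`, `n2`.
#' @examples
#' relative_risk(73, 859, 842, 18950)  # 1.9 (1.5, 2.4)
#' @export
relative_risk <- function(a, n1, b, n2, conf_level = 0.95) {
  stopifnot(length(a) == 1, length(n1) == 1, length(b) == 1, length(n2) == 1)
  if (n1 <= 0 || n2 <= 0) {
    rlang::abort("Group totals must be positive.", class = "ascertain_undefined")
  }
  if (a < 0 || b < 0 || a > n1 || b > n2) {
    rlang::abort("Expected 0 <= a <= n1 and 0 <= b <= n2.",
                 class = "ascertain_undefined")
  }
  rr <- (a / n1) / (b / n2)
  if (a == 0 || b == 0) {
    rlang::warn("Zero cell: relative-risk confidence interval is undefined.")
    lo <- hi <- NA_real_
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
    lo <- exp(log(rr) - z * se)
    hi <- exp(log(rr) + z * se)
  }
  new_ratio_estimate(tibble::tibble(
    estimate = rr, conf_low = lo, conf_high = hi, conf_level = conf_level,
    method = "lognormal_rr",
    a = as.integer(a), n1 = as.integer(n1),
    b = as.integer(b), n2 = as.integer(n2)
  ))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, with
#' `df = (r - 1)(c - 1)`. Warns when any expected cell count falls below 5.
#'
#' @param x Matrix or data frame of non-negative counts (r x c, r,c >= 2).
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `min_expected`.
#' @examples
#' chi_square_test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
chi_square_test <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || any(m < 0) || nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("`x` must be an r x c (r, c >= 2) table of non-negative counts.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    rlang::warn("Some expected cell counts are below 5; the chi-square approximation may be poor.")
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = unname(fit$p.value),
    min_expected = min(expected)
  )
}
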