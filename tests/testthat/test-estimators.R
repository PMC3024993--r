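test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(2.65, 1), 2.7)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(26.769, 1), 26.8)
})

test_that("shortfall percentage reproduces the linked-records headline values", {
  expect_equal(underestimation_pct(714, 975), 26.8)
  expect_equal(underestimation_pct(3060, 3143), 2.6)
  expect_equal(underestimation_pct(3060, 3172), 3.5)
  expect_equal(underestimation_pct(3060, 3696), 17.2)
  expect_equal(underestimation_pct(100, 100), 0)
  expect_error(underestimation_pct(5, 0), class = "ascertain_undefined")
  expect_error(underestimation_pct(10, 5), class = "ascertain_undefined")
})

test_that("excess percentage reproduces the ladder over the index baseline", {
  expect_equal(excess_pct(3060, 83), 2.7)
  expect_equal(excess_pct(3060, 112), 3.7)
  expect_equal(excess_pct(3060, 636), 20.8)
  expect_equal(excess_pct(42, 0), 0)
  expect_error(excess_pct(0, 5), class = "ascertain_undefined")
})

test_that("shortfall and excess are two views of the same ratio", {
  set.seed(42)
  for (i in 1:20) {
    o <- sample(50:500, 1)
    r <- o + sample(0:200, 1)
    u <- underestimation_pct(o, r, digits = NULL)
    e <- excess_pct(o, r - o, digits = NULL)
    expect_equal((1 - u / 100) * (1 + e / 100), 1, tolerance = 1e-12)
  }
})

test_that("Wilson interval matches the score interval from an independent route", {
  for (k in c(1, 7, 50, 714)) {
    for (n in c(k + 1, 10 * k + 3, 975)) {
      if (k > n) next
      w <- wilson_interval(k, n)
      ref <- suppressWarnings(stats::prop.test(k, n, correct = FALSE))$conf.int
      expect_equal(w$conf_low, ref[1], tolerance = 1e-9)
      expect_equal(w$conf_high, ref[2], tolerance = 1e-9)
    }
  }
})

test_that("Wilson bounds solve the score inequality (grid oracle)", {
  k <- 5; n <- 10
  w <- wilson_interval(k, n)
  z <- qnorm(0.975)
  grid <- seq(0.001, 0.999, by = 0.001)
  inside <- abs(k / n - grid) <= z * sqrt(grid * (1 - grid) / n)
  expect_equal(min(grid[inside]), w$conf_low, tolerance = 2e-3)
  expect_equal(max(grid[inside]), w$conf_high, tolerance = 2e-3)
})

test_that("Wilson interval behaves at the boundary and contracts with n", {
  w0 <- wilson_interval(0, 10)
  expect_equal(w0$conf_low, 0, tolerance = 1e-12)
  expect_gt(w0$conf_high, 0)
  for (mult in c(1, 4, 16)) {
    w <- wilson_interval(5 * mult, 10 * mult)
    expect_gt(w$conf_low, 0)
    expect_lt(w$conf_high, 1)
  }
  widths <- sapply(c(1, 4, 16), function(m) {
    w <- wilson_interval(5 * m, 10 * m); w$conf_high - w$conf_low
  })
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_interval(3, 0), class = "ascertain_undefined")
})

test_that("Wilson complement scale reports under-ascertainment percentages", {
  w <- wilson_interval(714, 975, complement = TRUE)
  expect_equal(round_half_up(w$estimate, 1), 26.8)
  expect_equal(round_half_up(w$conf_low, 1), 24.1)
  expect_equal(round_half_up(w$conf_high, 1), 29.6)
  expect_lt(w$conf_low, w$estimate)
  expect_gt(w$conf_high, w$estimate)
})

test_that("relative risk uses the Katz log-normal interval (hand oracle)", {
  rr <- relative_risk(10, 100, 5, 100)
  expect_equal(rr$estimate, 2)
  z <- qnorm(0.975)
  se <- sqrt(1 / 10 - 1 / 100 + 1 / 5 - 1 / 100)  # hand-derived: sqrt(0.28)
  expect_equal(rr$conf_low, exp(log(2) - z * se), tolerance = 1e-12)
  expect_equal(rr$conf_high, exp(log(2) + z * se), tolerance = 1e-12)

  same <- relative_risk(20, 200, 30, 300)
  expect_equal(same$estimate, 1)
})

test_that("relative risk is symmetric under swapping and inverting groups", {
  set.seed(7)
  for (i in 1:15) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    a <- sample(seq_len(n1), 1); b <- sample(seq_len(n2), 1)
    fwd <- relative_risk(a, n1, b, n2)
    rev <- relative_risk(b, n2, a, n1)
    expect_equal(fwd$estimate, 1 / rev$estimate, tolerance = 1e-12)
    expect_equal(fwd$conf_low, 1 / rev$conf_high, tolerance = 1e-12)
  }
})

test_that("zero cells flag the relative-risk interval as undefined", {
  expect_warning(rr <- relative_risk(0, 50, 5, 100), "undefined")
  expect_true(is.na(rr$conf_low) && is.na(rr$conf_high))
  expect_error(relative_risk(5, 0, 5, 10), class = "ascertain_undefined")
})

test_that("chi-square matches hand computation and brute-force expected counts", {
  res <- chi_square_test(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)  # 4 * 25/15
  expect_equal(res$df, 1)

  same <- chi_square_test(matrix(c(15, 30, 15, 30), 2, byrow = TRUE))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  suppressWarnings({
    r32 <- chi_square_test(matrix(c(5, 10, 8, 9, 12, 4), nrow = 3))
  })
  expect_equal(r32$df, 2)

  set.seed(11)
  for (i in 1:10) {
    m <- matrix(sample(20:80, 6, replace = TRUE), nrow = 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(chi_square_test(m)$statistic, sum((m - e)^2 / e),
                 tolerance = 1e-9)
  }
})

test_that("chi-square warns on small expected counts and rejects degenerate tables", {
  expect_warning(chi_square_test(matrix(c(1, 2, 3, 4), 2)), "below 5")
  expect_error(chi_square_test(matrix(1:3, ncol = 1)))
})
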