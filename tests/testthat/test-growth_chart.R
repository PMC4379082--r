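test_that("per-woman mean of the two operator readings", {
  expect_equal(mean_of_operators(20.0, 22.0), 21.0)
  expect_equal(mean_of_operators(18.4, 21.1), 19.75)
  expect_equal(mean_of_operators(17.3, 17.3), 17.3)
  expect_error(mean_of_operators(NA, 20), "missing")
  expect_error(mean_of_operators(c(20, 21), 20), "equal length")
})

test_that("Bland-Altman matches hand-computed bias, SD and limits", {
  pairs <- tibble::tibble(uh_op1_cm = c(10, 11, 12), uh_op2_cm = c(11, 11, 11))
  # differences -1, 0, 1
  ba <- bland_altman(pairs)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_equal(ba$n, 3L)

  ident <- tibble::tibble(uh_op1_cm = c(20, 25), uh_op2_cm = c(20, 25))
  ba0 <- bland_altman(ident)
  expect_equal(c(ba0$bias, ba0$sd_diff, ba0$loa_low, ba0$loa_high),
               c(0, 0, 0, 0))

  expect_error(bland_altman(tibble::tibble(uh_op1_cm = 20, uh_op2_cm = 21)),
               "at least 2")
})

test_that("Bland-Altman is antisymmetric under operator swap", {
  ph1 <- simulate_phase1(growth_model_params(), n_per_week = 30, seed = 4)
  ba12 <- bland_altman(ph1, "uh_op1_cm", "uh_op2_cm")
  ba21 <- bland_altman(ph1, "uh_op2_cm", "uh_op1_cm")
  expect_equal(ba12$bias, -ba21$bias)
  expect_equal(ba12$sd_diff, ba21$sd_diff)
  expect_equal(ba12$loa_low, -ba21$loa_high)
})

test_that("synthetic operator noise lands the agreement limits in the 2-3 cm band", {
  ph1 <- simulate_phase1(growth_model_params(), n_per_week = 200, seed = 8)
  ba <- bland_altman(ph1)
  # generating value: 1.96 * sqrt(2) * 0.9 = 2.49 cm
  expect_gt(abs(ba$loa_high), 2)
  expect_lt(abs(ba$loa_high), 3)
  expect_gt(abs(ba$loa_low), 2)
  expect_lt(abs(ba$loa_low), 3)
})

test_that("weekly percentiles follow the order-statistic oracle", {
  # constant week: all statistics collapse to the constant
  const <- tibble::tibble(week = rep(30L, 5), uh_op1_cm = 28, uh_op2_cm = 28)
  chart <- weekly_percentiles(const, weeks = 30)
  expect_equal(chart$mean_cm, 28)
  expect_equal(chart$sd_cm, 0)
  expect_equal(c(chart$p10_cm, chart$p50_cm, chart$p90_cm), c(28, 28, 28))

  # 1..100 under linear-interpolation quantiles: p50 = 50.5, p10 = 10.9, p90 = 90.1
  v <- as.numeric(1:100)
  hundred <- tibble::tibble(week = 25L, uh_op1_cm = v, uh_op2_cm = v)
  chart2 <- weekly_percentiles(hundred, weeks = 25)
  expect_equal(chart2$p50_cm, 50.5)
  expect_equal(chart2$p10_cm, unname(quantile(v, 0.1)))
  expect_equal(chart2$n, 100L)
})

test_that("charts name the weeks that lack data", {
  ph1 <- simulate_phase1(growth_model_params(), n_per_week = 5,
                         weeks = 24:30, seed = 2)
  expect_error(weekly_percentiles(ph1, weeks = 24:36), "31")
})

test_that("percentiles are monotone within weeks and recover generating quantiles", {
  ph1 <- simulate_phase1(growth_model_params(), n_per_week = 1000, seed = 13)
  chart <- weekly_percentiles(ph1)
  expect_true(all(chart$p10_cm <= chart$p50_cm & chart$p50_cm <= chart$p90_cm))
  # across weeks, monotone growth dominates the spread at this n
  expect_true(all(diff(chart$p50_cm) > 0))
  # true median at week 30 is 1 + 0.9 * 30 = 28 cm
  expect_equal(chart$p50_cm[chart$week == 30], 28.0, tolerance = 0.3 / 28)
  # p10/p90 approach the generating normal quantiles (woman SD 2, operator
  # mean-of-two SD 0.9/sqrt(2))
  sd_tot <- sqrt(4 + 0.81 / 2)
  expect_equal(chart$p90_cm[chart$week == 30], 28 + qnorm(0.9) * sd_tot,
               tolerance = 0.02)
})

test_that("growth charts round-trip through CSV and JSON", {
  ph1 <- simulate_phase1(growth_model_params(), n_per_week = 10, seed = 3)
  chart <- weekly_percentiles(ph1, site = "demo")
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  write_growth_chart(chart, csv)
  write_growth_chart(chart, json)
  back_csv <- read_growth_chart(csv, site = "demo")
  back_json <- read_growth_chart(json)
  expect_equal(as.data.frame(back_csv), as.data.frame(chart), tolerance = 1e-12)
  expect_equal(as.data.frame(back_json), as.data.frame(chart), tolerance = 1e-12)
  expect_identical(attr(back_json, "site"), "demo")
})
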