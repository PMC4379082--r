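test_that("gestational-age bands use half-open day intervals", {
  expect_equal(as.character(ga_to_band(167)), "20.0-23.6") # 23 w 6 d
  expect_equal(as.character(ga_to_band(168)), "24.0-35.6") # 24 w 0 d
  expect_equal(as.character(ga_to_band(251)), "24.0-35.6") # 35 w 6 d
  expect_equal(as.character(ga_to_band(252)), "36.0-40.6") # 36 w 0 d
  expect_equal(as.character(ga_to_band(286)), "36.0-40.6") # 40 w 6 d
  expect_error(ga_to_band(139), "eligibility window")
  expect_error(ga_to_band(287), "eligibility window")
})

test_that("both simulation phases are deterministic under a fixed seed", {
  p <- growth_model_params()
  expect_identical(simulate_phase1(p, 10, seed = 42),
                   simulate_phase1(p, 10, seed = 42))
  expect_false(identical(simulate_phase1(p, 10, seed = 42),
                         simulate_phase1(p, 10, seed = 43)))
  expect_identical(simulate_phase2(p, sampling_plan(), seed = 42),
                   simulate_phase2(p, sampling_plan(), seed = 42))
})

test_that("noise-free parameters collapse to the deterministic growth line", {
  p0 <- growth_model_params(intercept = 1.0, slope = 0.9,
                            between_woman_sd = 0, operator_sd = 0)
  ph1 <- simulate_phase1(p0, n_per_week = 3, weeks = 24, seed = 1)
  expect_equal(ph1$uh_op1_cm, rep(22.6, 3))
  expect_equal(ph1$uh_op2_cm, rep(22.6, 3))

  # operator noise off, woman-level noise on: the two readings agree exactly
  p_noop <- growth_model_params(operator_sd = 0)
  ph1b <- simulate_phase1(p_noop, n_per_week = 20, seed = 2)
  expect_equal(ph1b$uh_op1_cm, ph1b$uh_op2_cm)
})

test_that("evaluation cohorts honor the stratified sampling plan", {
  cohort <- simulate_phase2(growth_model_params(), sampling_plan(), seed = 5)
  expect_identical(nrow(cohort), 250L)
  tab <- table(cohort$ga_band)
  expect_identical(as.integer(tab[["20.0-23.6"]]), 50L)
  expect_identical(as.integer(tab[["24.0-35.6"]]), 100L)
  expect_identical(as.integer(tab[["36.0-40.6"]]), 100L)
  expect_true(all(cohort$ga_days >= 140 & cohort$ga_days < 287))

  single <- simulate_phase2(growth_model_params(),
                            sampling_plan(c("24.0-27.6" = 5L)), seed = 5)
  expect_identical(nrow(single), 5L)
  expect_true(all(single$ga_days >= 168 & single$ga_days < 196))
  expect_true(all(single$ga_band == "24.0-35.6"))
})

test_that("inter-operator differences match the normal-error oracle", {
  p <- growth_model_params() # operator_sd 0.9
  ph1 <- simulate_phase1(p, n_per_week = 500, seed = 9)
  d <- ph1$uh_op1_cm - ph1$uh_op2_cm
  # oracle: d ~ N(0, 2 * operator_sd^2)
  expected <- 2 * stats::pnorm(2.5 / (sqrt(2) * 0.9)) - 1
  expect_equal(mean(abs(d) <= 2.5), expected, tolerance = 0.02)
  expect_equal(stats::sd(d), sqrt(2) * 0.9, tolerance = 0.05)
})

test_that("expected uterine height increases with gestational week", {
  ph1 <- simulate_phase1(growth_model_params(), n_per_week = 400, seed = 21)
  means <- tapply(mean_of_operators(ph1$uh_op1_cm, ph1$uh_op2_cm), ph1$week, mean)
  expect_true(all(diff(means) > 0))
  # weekly means converge on intercept + slope * week
  expect_equal(as.numeric(means), 1.0 + 0.9 * (24:36), tolerance = 0.02)
})

test_that("parameter validation rejects impossible growth models and plans", {
  expect_error(growth_model_params(slope = 0), "slope")
  expect_error(growth_model_params(between_woman_sd = -1))
  expect_error(growth_model_params(operator_sd = -0.1))
  expect_error(simulate_phase1(growth_model_params(), 0, seed = 1), "n_per_week")
  expect_error(simulate_phase1(growth_model_params(), 10), "seed")
  expect_error(sampling_plan(c(bogus = 5L)), "named by design strata")
})
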