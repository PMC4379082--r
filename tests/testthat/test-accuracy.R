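test_that("dichotomization reproduces the published 2x2 reduction", {
  cc <- dichotomize(load_fixture("Argentina", "10-90"), "24.0-35.6")
  expect_equal(cc$tp, 126L)
  expect_equal(cc$fn, 12L)
  expect_equal(cc$fp, 104L)
  expect_equal(cc$tn, 42L)
})

test_that("dichotomization conserves totals and matches a 9-cell brute force", {
  withr::local_seed(101)
  for (i in 1:25) {
    ct <- random_crosstab()
    total <- sum(ct$count)
    for (ep in c("24.0-35.6", "20.0-35.6")) {
      cc <- dichotomize(ct, ep)
      expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, total)
      # brute force over the 9 cells
      spec <- endpoint_spec(ep)
      tp <- fp <- fn <- tn <- 0L
      for (j in seq_len(nrow(ct))) {
        pos <- as.character(ct$zone[j]) %in% spec$positive_zones
        case <- as.character(ct$ga_band[j]) %in% spec$case_bands
        if (pos && case) tp <- tp + ct$count[j]
        if (pos && !case) fp <- fp + ct$count[j]
        if (!pos && case) fn <- fn + ct$count[j]
        if (!pos && !case) tn <- tn + ct$count[j]
      }
      expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(tp, fp, fn, tn))
    }
  }
})

test_that("with an empty low row the wider endpoint only adds early-band mid counts", {
  grid <- expand.grid(zone = c("low", "mid", "high"),
                      ga_band = c("20.0-23.6", "24.0-35.6", "36.0-40.6"),
                      stringsAsFactors = FALSE)
  withr::local_seed(11)
  grid$count <- ifelse(grid$zone == "low", 0L, sample.int(30, 9))
  ct <- as_crosstab(grid, site = "s", tape = "t")
  cc24 <- dichotomize(ct, "24.0-35.6")
  cc20 <- dichotomize(ct, "20.0-35.6")
  early_mid <- ct$count[ct$zone == "mid" & ct$ga_band == "20.0-23.6"]
  expect_equal(cc20$tp, cc24$tp + early_mid)
})

test_that("sensitivity, specificity and Wald intervals match the published cells", {
  est <- sens_spec(dichotomize(load_fixture("Argentina", "10-90"), "24.0-35.6"))
  sens <- est[est$kind == "sensitivity", ]
  expect_equal(round(100 * sens$estimate, 1), 91.3) # 126/138
  expect_equal(sens$numerator, 126L)

  est2 <- sens_spec(dichotomize(load_fixture("Argentina", "90-10"), "20.0-35.6"))
  sens2 <- est2[est2$kind == "sensitivity", ]
  expect_equal(sens2$numerator, 154L)
  expect_equal(sens2$denominator, 177L)
  expect_equal(round(100 * sens2$estimate, 1), 87.0)
  expect_equal(round(100 * sens2$ci_low, 1), 82.1)
  expect_equal(round(100 * sens2$ci_high, 1), 92.0)
})

test_that("degenerate proportions clip at the boundary and empty margins error", {
  cc <- tibble::tibble(tp = 40L, fp = 3L, fn = 0L, tn = 17L)
  est <- sens_spec(cc)
  sens <- est[est$kind == "sensitivity", ]
  expect_equal(sens$estimate, 1)
  expect_equal(sens$ci_high, 1)

  # unclipped Wald may exceed 100% (as some published intervals do)
  est_ind <- sens_spec(dichotomize(load_fixture("India", "10-90"), "20.0-35.6"),
                       clip = FALSE)
  expect_gt(est_ind$ci_high[est_ind$kind == "sensitivity"], 1)

  expect_error(sens_spec(tibble::tibble(tp = 0L, fp = 2L, fn = 0L, tn = 2L)),
               "no cases")
  expect_error(sens_spec(tibble::tibble(tp = 2L, fp = 0L, fn = 1L, tn = 0L)),
               "no non-cases")
})

test_that("Clopper-Pearson intervals are available and contain the estimate", {
  cc <- dichotomize(load_fixture("Zambia", "50-50"), "24.0-35.6")
  est <- sens_spec(cc, method = "clopper-pearson")
  expect_true(all(est$ci_low <= est$estimate & est$estimate <= est$ci_high))
})

test_that("trapezoidal AUC agrees with the shoelace polygon oracle", {
  expect_equal(trapezoid_auc(c(0, 0, 1), c(0, 1, 1)), 1) # perfect point
  expect_equal(trapezoid_auc(c(0, 1), c(0, 1)), 0.5)     # chance diagonal
  withr::local_seed(77)
  for (i in 1:50) {
    fpr <- sort(c(0, runif(sample(1:6, 1)), 1))
    tpr <- c(0, sort(runif(length(fpr) - 2)), 1)
    expect_equal(trapezoid_auc(fpr, tpr), shoelace_auc(fpr, tpr),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves over the fixture operating points match published AUCs", {
  roc <- roc_curve(site_tabs("Argentina"), "20.0-35.6")
  expect_equal(round(roc$auc, 2), 0.69)
  expect_equal(nrow(roc$points), 5L)
  expect_true(!is.unsorted(roc$points$fpr))
  expect_true(all(roc$points$fpr >= 0 & roc$points$fpr <= 1))
  expect_true(roc$auc_ci_low <= roc$auc & roc$auc <= roc$auc_ci_high)

  roc_pak <- roc_curve(site_tabs("Pakistan"), "24.0-35.6")
  expect_equal(round(roc_pak$auc, 2), 0.72)

  # a perfect single-tape curve
  grid <- expand.grid(zone = c("low", "mid", "high"),
                      ga_band = c("20.0-23.6", "24.0-35.6", "36.0-40.6"),
                      stringsAsFactors = FALSE)
  grid$count <- with(grid, ifelse(
    (zone == "low" & ga_band == "20.0-23.6") |
      (zone == "mid" & ga_band == "24.0-35.6") |
      (zone == "high" & ga_band == "36.0-40.6"), 10L, 0L))
  perfect <- as_crosstab(grid, site = "p", tape = "t")
  expect_equal(roc_curve(list(perfect), "24.0-35.6")$auc, 1)

  expect_error(roc_curve(site_tabs("India")[1:2] |>
                           c(site_tabs("Zambia")[3]), "24.0-35.6"),
               "one site")
})

test_that("cross-tabulation counts zones by band and tracks exclusions", {
  cohort <- tibble::tibble(ga_days = c(200L, 160L, 260L, 210L),
                           uh_cm = c(25, 15, 36, NA))
  tape <- tape_spec(20, 34, name = "demo", site = "demo")
  ct <- crosstab(cohort, tape)
  expect_s3_class(ct, "uh_crosstab")
  expect_equal(sum(ct$count), 3L)
  expect_equal(attr(ct, "n_excluded"), 1L)
  expect_equal(ct$count[ct$zone == "mid" & ct$ga_band == "24.0-35.6"], 1L)
  expect_equal(ct$count[ct$zone == "low" & ct$ga_band == "20.0-23.6"], 1L)
  expect_equal(ct$count[ct$zone == "high" & ct$ga_band == "36.0-40.6"], 1L)
  expect_error(crosstab(cohort[0, ], tape), "empty cohort")

  full <- simulate_phase2(growth_model_params(), sampling_plan(), seed = 2)
  ct2 <- crosstab(full, tape)
  expect_equal(sum(ct2$count) + attr(ct2, "n_excluded"), 250L)
})

test_that("prevalence projection reproduces the published worked example", {
  proj <- predictive_projection(0.777, 0.886, 0.20)
  expect_equal(round(proj$classified_positive_pct), 25)
  expect_equal(round(proj$tp_pct), 16)
  expect_equal(round(proj$fp_pct), 9)
  expect_equal(round(proj$tn_pct), 71)
  expect_equal(round(proj$fn_pct), 4)

  ideal <- predictive_projection(1, 1, 0.3)
  expect_equal(ideal$classified_positive_pct, 30)
  expect_equal(ideal$fp_pct, 0)
  expect_equal(ideal$fn_pct, 0)

  withr::local_seed(5)
  for (i in 1:20) {
    p <- predictive_projection(runif(1), runif(1), runif(1))
    expect_equal(p$tp_pct + p$fp_pct + p$tn_pct + p$fn_pct, 100)
    expect_equal(p$classified_positive_pct, p$tp_pct + p$fp_pct)
  }
  expect_error(predictive_projection(1.2, 0.5, 0.5), "proportions")
})
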