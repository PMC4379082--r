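#' Growth-model parameters for synthetic cohorts
#'
#' The synthetic generator assumes uterine height (UH) grows linearly with
#' gestational age: for a woman at completed week \eqn{w},
#' \deqn{UH = intercept + slope \cdot w + b + e,}
#' where \eqn{b \sim N(0, between\_woman\_sd^2)} is a stable woman-level
#' deviation and \eqn{e \sim N(0, operator\_sd^2)} is independent measurement
#' error added to each operator reading.
#'
#' The defaults give a clinically plausible curve, roughly 1 cm per week:
#' about 22.6 cm at 24 weeks and 33.4 cm at 36 weeks, a between-woman spread
#' of a few cm, and 95% limits of inter-operator agreement of
#' \eqn{1.96\sqrt{2}\cdot 0.9 \approx 2.5} cm, inside the 2-3 cm band the
#' calibration-phase agreement analysis reported.
#'
#' @param intercept Intercept of the linear growth curve (cm).
#' @param slope Growth per gestational week (cm/week); must be positive.
#' @param between_woman_sd SD of the woman-level deviation (cm); non-negative.
#' @param operator_sd SD of a single operator reading's error (cm);
#'   non-negative.
#' @param site Label attached to data generated under these parameters.
#' @return A list of class `uh_growth_params`.
#' @examples
#' growth_model_params()
#' growth_model_params(operator_sd = 0)
#' @export
growth_model_params <- function(intercept = 1.0, slope = 0.9,
                                between_woman_sd = 2.0, operator_sd = 0.9,
                                site = "synthetic") {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(slope), length(slope) == 1L,
            is.numeric(between_woman_sd), length(between_woman_sd) == 1L,
            is.numeric(operator_sd), length(operator_sd) == 1L)
  if (slope <= 0) abort("`slope` must be > 0: expected UH must increase with GA.")
  if (between_woman_sd < 0) abort("`between_woman_sd` must be >= 0.")
  if (operator_sd < 0) abort("`operator_sd` must be >= 0.")
  structure(
    list(intercept = intercept, slope = slope,
         between_woman_sd = between_woman_sd, operator_sd = operator_sd,
         site = site),
    class = "uh_growth_params"
  )
}

#' @export
print.uh_growth_params <- function(x, ...) {
  cat("<uh_growth_params>", x$site, "\n")
  cat(sprintf("  UH = %.2f + %.2f * week (cm); between-woman SD %.2f, operator SD %.2f\n",
              x$intercept, x$slope, x$between_woman_sd, x$operator_sd))
  invisible(x)
}

#' Stratified sampling plan for an evaluation cohort
#'
#' The evaluation phase enrolled a fixed gestational-age distribution per
#' site: 50 women at 20.0-23.6 weeks, 100 in the preterm window (10 at
#' 24.0-27.6, 20 at 28.0-31.6, 70 at 32.0-35.6 weeks) and 100 at 36.0-40.6
#' weeks, 250 in all. These are the default stratum targets; the preterm
#' stratification approximates the gestational-age distribution expected
#' among preterm births at the study sites.
#'
#' @param counts Named integer vector of target counts per stratum. Names
#'   must be a subset of the five design strata
#'   `20.0-23.6`, `24.0-27.6`, `28.0-31.6`, `32.0-35.6`, `36.0-40.6`.
#' @return A tibble of class `uh_sampling_plan` with columns `stratum`,
#'   `ga_min_days`, `ga_max_days` (exclusive) and `n`.
#' @examples
#' sampling_plan()
#' sampling_plan(c("24.0-27.6" = 5))
#' @export
sampling_plan <- function(counts = c("20.0-23.6" = 50L, "24.0-27.6" = 10L,
                                     "28.0-31.6" = 20L, "32.0-35.6" = 70L,
                                     "36.0-40.6" = 100L)) {
  strata <- tibble(
    stratum = c("20.0-23.6", "24.0-27.6", "28.0-31.6", "32.0-35.6", "36.0-40.6"),
    ga_min_days = c(140L, 168L, 196L, 224L, 252L),
    ga_max_days = c(168L, 196L, 224L, 252L, 287L)
  )
  if (is.null(names(counts)) || !all(names(counts) %in% strata$stratum)) {
    abort("`counts` must be named by design strata (e.g. \"20.0-23.6\").")
  }
  if (any(counts < 0) || anyNA(counts)) abort("stratum counts must be non-negative.")
  plan <- dplyr::inner_join(
    strata,
    tibble(stratum = names(counts), n = as.integer(counts)),
    by = "stratum"
  )
  plan <- dplyr::filter(plan, .data$n > 0L)
  if (nrow(plan) == 0L) abort("sampling plan has no non-empty stratum.")
  structure(plan, class = c("uh_sampling_plan", class(tibble())))
}

#' Simulate calibration-phase paired measurements
#'
#' Generates the data structure of the tape-calibration phase: for each
#' completed week of gestation in `weeks`, `n_per_week` women, each measured
#' independently by two operators. True UH follows the linear growth model in
#' `params`; each operator reading adds independent normal error. Gestational
#' age within a week is drawn uniformly at day resolution, but the growth
#' model is evaluated at the completed week, matching a per-week chart.
#'
#' @param params A [growth_model_params()] object.
#' @param n_per_week Women per completed week (>= 1).
#' @param weeks Integer vector of completed weeks (default 24 to 36).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `params`, `n_per_week`, `weeks` and `seed`.
#' @return A tibble with columns `subject_id`, `ga_days`, `week`,
#'   `uh_op1_cm`, `uh_op2_cm`.
#' @examples
#' simulate_phase1(growth_model_params(), n_per_week = 5, seed = 1)
#' @export
simulate_phase1 <- function(params = growth_model_params(), n_per_week = 40L,
                            weeks = 24:36, seed) {
  stopifnot(inherits(params, "uh_growth_params"))
  if (missing(seed)) abort("`seed` is required: simulations must be reproducible.")
  n_per_week <- as.integer(n_per_week)
  if (is.na(n_per_week) || n_per_week < 1L) abort("`n_per_week` must be >= 1.")
  weeks <- as.integer(weeks)
  if (length(weeks) == 0L || anyNA(weeks) || any(weeks < 0L)) {
    abort("`weeks` must be a non-empty vector of non-negative completed weeks.")
  }
  n <- n_per_week * length(weeks)
  withr::with_seed(seed, {
    week <- rep(sort(weeks), each = n_per_week)
    day_in_week <- sample.int(7L, n, replace = TRUE) - 1L
    true_uh <- params$intercept + params$slope * week +
      rnorm(n, 0, params$between_woman_sd)
    tibble(
      subject_id = sprintf("P1-%04d", seq_len(n)),
      ga_days = week * 7L + day_in_week,
      week = week,
      uh_op1_cm = true_uh + rnorm(n, 0, params$operator_sd),
      uh_op2_cm = true_uh + rnorm(n, 0, params$operator_sd)
    )
  })
}

#' Simulate an evaluation-phase cohort
#'
#' Generates a single-measurement cohort following a stratified sampling
#' plan: within each stratum gestational age is uniform at day resolution,
#' and each woman contributes one masked UH reading with combined
#' woman-level and operator noise,
#' \eqn{SD = \sqrt{between\_woman\_sd^2 + operator\_sd^2}}. The growth model
#' is evaluated at continuous gestational age in weeks (`ga_days / 7`).
#'
#' @param params A [growth_model_params()] object.
#' @param plan A [sampling_plan()] tibble.
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `ga_days`, `ga_band`
#'   (three-level reporting band) and `uh_cm`; stratum counts match the plan
#'   exactly.
#' @examples
#' cohort <- simulate_phase2(growth_model_params(), sampling_plan(), seed = 1)
#' table(cohort$ga_band)
#' @export
simulate_phase2 <- function(params = growth_model_params(),
                            plan = sampling_plan(), seed) {
  stopifnot(inherits(params, "uh_growth_params"))
  if (missing(seed)) abort("`seed` is required: simulations must be reproducible.")
  if (!inherits(plan, "uh_sampling_plan")) abort("`plan` must be a `sampling_plan()`.")
  if (any(plan$ga_max_days <= plan$ga_min_days)) abort("empty stratum bounds in plan.")
  total_sd <- sqrt(params$between_woman_sd^2 + params$operator_sd^2)
  withr::with_seed(seed, {
    ga_days <- unlist(purrr::pmap(
      list(plan$ga_min_days, plan$ga_max_days, plan$n),
      function(lo, hi, n) lo + sample.int(hi - lo, n, replace = TRUE) - 1L
    ))
    n <- length(ga_days)
    tibble(
      subject_id = sprintf("P2-%04d", seq_len(n)),
      ga_days = as.integer(ga_days),
      ga_band = ga_to_band(ga_days),
      uh_cm = params$intercept + params$slope * (ga_days / 7) +
        rnorm(n, 0, total_sd)
    )
  })
}
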