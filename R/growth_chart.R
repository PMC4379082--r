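#' Mean of two operator readings
#'
#' Each calibration-phase woman is measured by two independent operators;
#' once agreement is acceptable, her working UH value is the arithmetic mean
#' of the two readings. Missing readings are an error — no imputation.
#'
#' @param op1,op2 Numeric vectors of paired readings (cm).
#' @return Numeric vector of per-woman means.
#' @examples
#' mean_of_operators(20, 22)
#' @export
mean_of_operators <- function(op1, op2) {
  if (length(op1) != length(op2)) abort("`op1` and `op2` must have equal length.")
  if (anyNA(op1) || anyNA(op2)) abort("missing operator reading: both readings are required.")
  if (any(op1 <= 0) || any(op2 <= 0)) abort("operator readings must be positive (cm).")
  (op1 + op2) / 2
}

#' Bland-Altman agreement between two operators
#'
#' Computes the mean difference (bias) between the first and second operator
#' readings, the sample SD of the differences, and the 95% limits of
#' agreement `bias +/- 1.96 * sd_diff`. Under the default synthetic operator
#' noise (SD 0.9 cm per reading) the limits are about +/- 2.5 cm, i.e. 95%
#' of paired readings differ by less than about 2.5 cm.
#'
#' @param pairs A data frame of paired measurements with the columns named
#'   by `op1` and `op2`.
#' @param op1,op2 Column names of the two readings (default `uh_op1_cm`,
#'   `uh_op2_cm`, as produced by [simulate_phase1()]).
#' @return An object of class `uh_bland_altman` with elements `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, and the per-pair `differences`
#'   and `means` used for plotting. [tidy()] returns the summary as a
#'   one-row tibble; [autoplot()] draws the standard agreement plot.
#' @examples
#' ph1 <- simulate_phase1(growth_model_params(), n_per_week = 20, seed = 1)
#' bland_altman(ph1)
#' @export
bland_altman <- function(pairs, op1 = "uh_op1_cm", op2 = "uh_op2_cm") {
  stopifnot(is.data.frame(pairs))
  if (!all(c(op1, op2) %in% names(pairs))) {
    abort(sprintf("`pairs` must contain columns `%s` and `%s`.", op1, op2))
  }
  x <- pairs[[op1]]
  y <- pairs[[op2]]
  if (anyNA(x) || anyNA(y)) abort("missing operator reading: both readings are required.")
  n <- length(x)
  if (n < 2L) abort("Bland-Altman needs at least 2 pairs (SD of differences undefined).")
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         n = n, differences = d, means = (x + y) / 2),
    class = "uh_bland_altman"
  )
}

#' @export
print.uh_bland_altman <- function(x, ...) {
  cat("<uh_bland_altman>", x$n, "pairs\n")
  cat(sprintf("  bias %.3f cm, SD of differences %.3f cm\n", x$bias, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: %.3f to %.3f cm\n", x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `uh_bland_altman` object.
#' @param ... Unused.
#' @method tidy uh_bland_altman
#' @export
tidy.uh_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' @rdname bland_altman
#' @method glance uh_bland_altman
#' @export
glance.uh_bland_altman <- function(x, ...) tidy.uh_bland_altman(x)

#' Per-week uterine-height percentile chart
#'
#' Summarises calibration-phase data into a growth chart: for each completed
#' week of gestation, the number of women and the mean, SD, 10th, 50th and
#' 90th percentiles of the per-woman mean UH (the average of the two
#' operator readings). Quantiles use linear interpolation between order
#' statistics (R type 7) by default; the estimator is exposed because
#' percentile charts are sensitive to it at small n.
#'
#' @param pairs A data frame of paired measurements (see [simulate_phase1()]);
#'   must contain `ga_days` (or `week`) plus the two reading columns.
#' @param site Chart label (whose population the chart describes).
#' @param weeks Completed weeks the chart must cover (default 24 to 36). Every
#'   requested week must have at least 2 women.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @param op1,op2 Column names of the two readings.
#' @return A tibble of class `uh_growth_chart` with columns `week`, `n`,
#'   `mean_cm`, `sd_cm`, `p10_cm`, `p50_cm`, `p90_cm`, and a `site`
#'   attribute. Rows are sorted by week.
#' @examples
#' ph1 <- simulate_phase1(growth_model_params(), n_per_week = 30, seed = 1)
#' weekly_percentiles(ph1)
#' @export
weekly_percentiles <- function(pairs, site = "synthetic", weeks = 24:36,
                               quantile_type = 7,
                               op1 = "uh_op1_cm", op2 = "uh_op2_cm") {
  stopifnot(is.data.frame(pairs))
  weeks <- sort(as.integer(weeks))
  if ("week" %in% names(pairs)) {
    wk <- as.integer(pairs$week)
  } else if ("ga_days" %in% names(pairs)) {
    wk <- as.integer(floor(pairs$ga_days / 7))
  } else {
    abort("`pairs` must contain a `week` or `ga_days` column.")
  }
  uh <- mean_of_operators(pairs[[op1]], pairs[[op2]])
  dat <- tibble(week = wk, uh = uh)
  counts <- dplyr::count(dplyr::filter(dat, .data$week %in% weeks), .data$week)
  missing_weeks <- setdiff(weeks, counts$week[counts$n >= 2L])
  if (length(missing_weeks) > 0L) {
    abort(paste0("fewer than 2 subjects in week(s): ",
                 paste(missing_weeks, collapse = ", ")))
  }
  chart <- dat |>
    dplyr::filter(.data$week %in% weeks) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cm = mean(.data$uh),
      sd_cm = stats::sd(.data$uh),
      p10_cm = unname(quantile(.data$uh, 0.10, type = quantile_type)),
      p50_cm = unname(quantile(.data$uh, 0.50, type = quantile_type)),
      p90_cm = unname(quantile(.data$uh, 0.90, type = quantile_type)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$week)
  new_growth_chart(chart, site = site)
}

new_growth_chart <- function(chart, site) {
  stopifnot(all(c("week", "n", "mean_cm", "sd_cm", "p10_cm", "p50_cm", "p90_cm")
                %in% names(chart)))
  if (any(chart$p10_cm > chart$p50_cm | chart$p50_cm > chart$p90_cm)) {
    abort("growth chart violates p10 <= p50 <= p90 within a week.")
  }
  structure(as_tibble(chart), site = site,
            class = c("uh_growth_chart", class(tibble())))
}

#' Build a growth chart from pre-computed per-week summaries
#'
#' Escape hatch for charts whose per-week percentiles come from elsewhere
#' (e.g. a published regional chart): validates monotone percentiles and
#' returns the same object [weekly_percentiles()] produces.
#'
#' @param chart A data frame with columns `week`, `n`, `mean_cm`, `sd_cm`,
#'   `p10_cm`, `p50_cm`, `p90_cm`.
#' @param site Chart label.
#' @return A `uh_growth_chart` tibble.
#' @export
as_growth_chart <- function(chart, site = "external") {
  new_growth_chart(as_tibble(chart), site = site)
}

chart_site <- function(chart) attr(chart, "site", exact = TRUE) %||% "unknown"

#' Write / read a growth chart
#'
#' Charts serialise to CSV (columns `week`, `n`, `mean_cm`, `sd_cm`,
#' `p10_cm`, `p50_cm`, `p90_cm`) or JSON, chosen by the file extension.
#'
#' @param chart A `uh_growth_chart`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly (`write_growth_chart`); a `uh_growth_chart`
#'   (`read_growth_chart`).
#' @export
write_growth_chart <- function(chart, path) {
  stopifnot(inherits(chart, "uh_growth_chart"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    write.csv(as.data.frame(chart), path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(
      list(site = chart_site(chart), chart = as.data.frame(chart)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    abort("unsupported growth chart format: use .csv or .json")
  }
  invisible(path)
}

#' @rdname write_growth_chart
#' @param site Site label to attach when reading CSV (JSON stores its own).
#' @export
read_growth_chart <- function(path, site = "external") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    new_growth_chart(as_tibble(read.csv(path)), site = site)
  } else if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_growth_chart(as_tibble(x$chart), site = x$site)
  } else {
    abort("unsupported growth chart format: use .csv or .json")
  }
}
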