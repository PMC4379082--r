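#' Cross-tabulate tape zones against gestational-age bands
#'
#' Classifies every subject's UH with the tape and counts zone by reporting
#' band, the 3 x 3 table from which all accuracy statistics derive. Subjects
#' with a missing UH are excluded from the table and reported in the
#' `n_excluded` attribute, so per-tape denominators reflect the measurements
#' actually taken with that tape.
#'
#' @param cohort A data frame with columns `uh_cm` and either `ga_band` or
#'   `ga_days` (see [simulate_phase2()]).
#' @param tape A `uh_tape`.
#' @param boundary Boundary convention passed to [classify_uh()].
#' @param site Site label; defaults to the tape's source site.
#' @return A tibble of class `uh_crosstab` with columns `site`, `tape`,
#'   `zone`, `ga_band`, `count` (9 rows, zero cells included) and attributes
#'   `site`, `tape`, `n_excluded`.
#' @examples
#' cohort <- simulate_phase2(growth_model_params(), sampling_plan(), seed = 1)
#' crosstab(cohort, tape_spec(22.6, 33.4, name = "50-50"))
#' @export
crosstab <- function(cohort, tape, boundary = c("lower-closed", "mid-closed"),
                     site = NULL) {
  stopifnot(is.data.frame(cohort), inherits(tape, "uh_tape"))
  boundary <- match.arg(boundary)
  if (nrow(cohort) == 0L) abort("empty cohort: nothing to cross-tabulate.")
  if (!"uh_cm" %in% names(cohort)) abort("`cohort` must contain `uh_cm`.")
  if (!"ga_band" %in% names(cohort)) {
    if (!"ga_days" %in% names(cohort)) {
      abort("`cohort` must contain `ga_band` or `ga_days`.")
    }
    cohort$ga_band <- ga_to_band(cohort$ga_days)
  }
  site <- site %||% tape$site
  keep <- !is.na(cohort$uh_cm)
  n_excluded <- sum(!keep)
  cohort <- cohort[keep, ]
  if (nrow(cohort) == 0L) abort("all subjects have missing UH.")
  counts <- tibble(
    zone = classify_uh(tape, cohort$uh_cm, boundary = boundary),
    ga_band = band_factor(cohort$ga_band)
  ) |>
    dplyr::count(.data$zone, .data$ga_band, .drop = FALSE, name = "count")
  new_crosstab(
    tibble(site = site, tape = tape$name,
           zone = counts$zone, ga_band = counts$ga_band, count = counts$count),
    site = site, tape = tape$name, n_excluded = n_excluded
  )
}

new_crosstab <- function(df, site, tape, n_excluded = 0L) {
  stopifnot(all(c("site", "tape", "zone", "ga_band", "count") %in% names(df)))
  if (any(df$count < 0)) abort("cross-tab counts must be non-negative.")
  df$zone <- zone_factor(df$zone)
  df$ga_band <- band_factor(df$ga_band)
  df <- dplyr::arrange(df, .data$zone, .data$ga_band)
  if (nrow(df) != 9L || anyNA(df$zone) || anyNA(df$ga_band)) {
    abort("a cross-tab needs exactly the 9 zone x band cells.")
  }
  structure(as_tibble(df), site = site, tape = tape,
            n_excluded = as.integer(n_excluded),
            class = c("uh_crosstab", class(tibble())))
}

#' Assemble a cross-tab from pre-counted cells
#'
#' Accepts externally tabulated zone-by-band counts (e.g. published tables)
#' as a `uh_crosstab`, the same container [crosstab()] produces.
#'
#' @param df A data frame with columns `zone`, `ga_band`, `count` (and
#'   optionally `site`, `tape`).
#' @param site,tape Labels; taken from `df` if present.
#' @param n_excluded Measurements excluded from the table, if known.
#' @return A `uh_crosstab` tibble.
#' @export
as_crosstab <- function(df, site = NULL, tape = NULL, n_excluded = 0L) {
  df <- as_tibble(df)
  site <- site %||% unique(as.character(df$site))
  tape <- tape %||% unique(as.character(df$tape))
  if (length(site) != 1L || length(tape) != 1L) {
    abort("`site` and `tape` must each resolve to a single label.")
  }
  df$site <- site
  df$tape <- tape
  new_crosstab(df[c("site", "tape", "zone", "ga_band", "count")],
               site = site, tape = tape, n_excluded = n_excluded)
}

crosstab_total <- function(ct) sum(ct$count)

#' Endpoint definitions
#'
#' The three-zone reading is reduced to a binary test for one of two target
#' gestational-age ranges:
#' * `"24.0-35.6"` — identify the preterm ACS window; a positive test is a
#'   measurement in the mid (red) zone; cases are the 24.0-35.6 week band.
#' * `"20.0-35.6"` — identify any pregnancy up to 35.6 weeks; a positive
#'   test is a measurement in the mid or low (red or yellow) zones; cases
#'   are the 20.0-23.6 and 24.0-35.6 week bands.
#'
#' @param endpoint `"24.0-35.6"` or `"20.0-35.6"`.
#' @return A list with `endpoint`, `positive_zones`, `case_bands`.
#' @examples
#' endpoint_spec("24.0-35.6")
#' @export
endpoint_spec <- function(endpoint = c("24.0-35.6", "20.0-35.6")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "24.0-35.6") {
    list(endpoint = endpoint, positive_zones = "mid", case_bands = "24.0-35.6")
  } else {
    list(endpoint = endpoint, positive_zones = c("mid", "low"),
         case_bands = c("20.0-23.6", "24.0-35.6"))
  }
}

#' Reduce a cross-tab to confusion counts for an endpoint
#'
#' @param ct A `uh_crosstab`.
#' @param endpoint Endpoint label (see [endpoint_spec()]).
#' @return A one-row tibble with columns `site`, `tape`, `endpoint`, `tp`,
#'   `fp`, `fn`, `tn`; `tp + fp + fn + tn` equals the cross-tab total.
#' @examples
#' dichotomize(load_fixture("Argentina", "10-90"), "24.0-35.6")
#' @export
dichotomize <- function(ct, endpoint = c("24.0-35.6", "20.0-35.6")) {
  stopifnot(inherits(ct, "uh_crosstab"))
  ep <- endpoint_spec(match.arg(endpoint))
  pos <- ct$zone %in% ep$positive_zones
  case <- ct$ga_band %in% ep$case_bands
  tibble(
    site = attr(ct, "site"), tape = attr(ct, "tape"), endpoint = ep$endpoint,
    tp = sum(ct$count[pos & case]), fp = sum(ct$count[pos & !case]),
    fn = sum(ct$count[!pos & case]), tn = sum(ct$count[!pos & !case])
  )
}

#' Sensitivity and specificity with binomial confidence intervals
#'
#' Sensitivity is `tp / (tp + fn)`, specificity `tn / (tn + fp)`. The default
#' 95% interval is the Wald normal approximation
#' `p +/- 1.96 sqrt(p (1 - p) / n)`, which reproduces the published
#' intervals; Clopper-Pearson exact intervals are available. Wald limits are
#' clipped to `[0, 1]` unless `clip = FALSE`.
#'
#' @param cc A one-row confusion-count tibble from [dichotomize()], or any
#'   data frame with columns `tp`, `fp`, `fn`, `tn`.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"clopper-pearson"`.
#' @param clip Clip Wald limits to `[0, 1]` (default `TRUE`).
#' @return A two-row tibble (`kind` = `sensitivity`, `specificity`) with
#'   `estimate`, `ci_low`, `ci_high` (proportions) and `numerator`,
#'   `denominator`; identifying columns of `cc` are carried through.
#' @examples
#' load_fixture("Argentina", "10-90") |>
#'   dichotomize("24.0-35.6") |>
#'   sens_spec()
#' @export
sens_spec <- function(cc, conf_level = 0.95,
                      method = c("wald", "clopper-pearson"), clip = TRUE) {
  stopifnot(is.data.frame(cc), nrow(cc) == 1L,
            all(c("tp", "fp", "fn", "tn") %in% names(cc)))
  method <- match.arg(method)
  cases <- cc$tp + cc$fn
  noncases <- cc$fp + cc$tn
  if (cases < 1L) abort("no cases: sensitivity denominator is zero.")
  if (noncases < 1L) abort("no non-cases: specificity denominator is zero.")
  ids <- cc[intersect(c("site", "tape", "endpoint"), names(cc))]
  one <- function(kind, x, n) {
    p <- x / n
    ci <- binom_ci(x, n, conf_level = conf_level, method = method, clip = clip)
    dplyr::bind_cols(ids, tibble(
      kind = kind, estimate = p, ci_low = ci[1], ci_high = ci[2],
      numerator = x, denominator = n
    ))
  }
  dplyr::bind_rows(one("sensitivity", cc$tp, cases),
                   one("specificity", cc$tn, noncases))
}

binom_ci <- function(x, n, conf_level = 0.95,
                     method = c("wald", "clopper-pearson"), clip = TRUE) {
  method <- match.arg(method)
  p <- x / n
  if (method == "wald") {
    z <- qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(p - half, p + half)
    if (clip) ci <- pmin(pmax(ci, 0), 1)
    ci
  } else {
    unname(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
  }
}

#' Per-tape accuracy for both endpoints
#'
#' Convenience wrapper: [dichotomize()] then [sens_spec()] for each requested
#' endpoint, returning one tidy row per statistic.
#'
#' @param ct A `uh_crosstab`.
#' @param endpoints Endpoints to evaluate (default both).
#' @inheritParams sens_spec
#' @return A tibble with columns `site`, `tape`, `endpoint`, `kind`,
#'   `estimate`, `ci_low`, `ci_high`, `numerator`, `denominator`.
#' @examples
#' tape_accuracy(load_fixture("Pakistan", "90-10"))
#' @export
tape_accuracy <- function(ct, endpoints = c("24.0-35.6", "20.0-35.6"),
                          conf_level = 0.95,
                          method = c("wald", "clopper-pearson"), clip = TRUE) {
  method <- match.arg(method)
  purrr::map_dfr(endpoints, function(ep) {
    sens_spec(dichotomize(ct, ep), conf_level = conf_level,
              method = method, clip = clip)
  })
}

#' Empirical ROC curve over tape operating points
#'
#' Each tape design supplies one operating point,
#' `(1 - specificity, sensitivity)`, computed on that tape's own
#' denominators. The curve is the point set augmented with `(0, 0)` and
#' `(1, 1)`, sorted by false-positive rate (ties kept in tape order and
#' averaged implicitly by the trapezoid), and the AUC is its trapezoidal
#' area. The AUC confidence interval uses the Hanley-McNeil standard error
#' with the average case/non-case counts across tapes; it is reported for
#' orientation only and is not part of the published-table reproduction.
#'
#' @param tabs List of `uh_crosstab` objects for one site (one per tape).
#' @param endpoint Endpoint label.
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `uh_roc` with `site`, `endpoint`, `points`
#'   (tibble `tape`, `fpr`, `tpr` including the anchors), `auc`,
#'   `auc_ci_low`, `auc_ci_high`. [tidy()] returns the points, [glance()]
#'   the AUC row.
#' @examples
#' tabs <- lapply(c("10-90", "50-50", "90-10"), load_fixture, site = "Argentina")
#' roc_curve(tabs, "20.0-35.6")
#' @export
roc_curve <- function(tabs, endpoint = c("24.0-35.6", "20.0-35.6"),
                      conf_level = 0.95) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.list(tabs), length(tabs) >= 1L)
  purrr::walk(tabs, ~ stopifnot(inherits(.x, "uh_crosstab")))
  sites <- unique(purrr::map_chr(tabs, ~ attr(.x, "site")))
  if (length(sites) != 1L) abort("all cross-tabs must come from one site.")
  ops <- purrr::map_dfr(tabs, function(ct) {
    cc <- dichotomize(ct, endpoint)
    tibble(tape = attr(ct, "tape"),
           fpr = cc$fp / (cc$fp + cc$tn),
           tpr = cc$tp / (cc$tp + cc$fn),
           cases = cc$tp + cc$fn, noncases = cc$fp + cc$tn)
  })
  pts <- dplyr::bind_rows(
    tibble(tape = "(0,0)", fpr = 0, tpr = 0),
    dplyr::arrange(ops[c("tape", "fpr", "tpr")], .data$fpr, .data$tpr),
    tibble(tape = "(1,1)", fpr = 1, tpr = 1)
  )
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  se <- hanley_mcneil_se(auc, mean(ops$cases), mean(ops$noncases))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(site = sites, endpoint = endpoint, points = pts, auc = auc,
         auc_ci_low = max(0, auc - z * se),
         auc_ci_high = min(1, auc + z * se)),
    class = "uh_roc"
  )
}

#' Trapezoidal area under a piecewise-linear curve
#'
#' @param fpr,tpr Coordinates sorted by `fpr`, both in `[0, 1]`.
#' @return The trapezoidal area.
#' @examples
#' trapezoid_auc(c(0, 0.5, 1), c(0, 0.9, 1))
#' @export
trapezoid_auc <- function(fpr, tpr) {
  stopifnot(length(fpr) == length(tpr), length(fpr) >= 2L,
            !is.unsorted(fpr), all(fpr >= 0 & fpr <= 1), all(tpr >= 0 & tpr <= 1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

hanley_mcneil_se <- function(auc, n_cases, n_noncases) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
          (n_noncases - 1) * (q2 - auc^2)) / (n_cases * n_noncases))
}

#' @export
print.uh_roc <- function(x, ...) {
  cat(sprintf("<uh_roc> %s, endpoint %s\n", x$site, x$endpoint))
  cat(sprintf("  AUC %.3f (%.3f, %.3f), %d operating points\n",
              x$auc, x$auc_ci_low, x$auc_ci_high, nrow(x$points) - 2L))
  invisible(x)
}

#' @rdname roc_curve
#' @param x A `uh_roc` object.
#' @param ... Unused.
#' @method tidy uh_roc
#' @export
tidy.uh_roc <- function(x, ...) {
  dplyr::mutate(x$points, site = x$site, endpoint = x$endpoint,
                .before = 1L)
}

#' @rdname roc_curve
#' @method glance uh_roc
#' @export
glance.uh_roc <- function(x, ...) {
  tibble(site = x$site, endpoint = x$endpoint, auc = x$auc,
         auc_ci_low = x$auc_ci_low, auc_ci_high = x$auc_ci_high,
         n_points = nrow(x$points) - 2L)
}

#' Project screening yield at a working prevalence
#'
#' Translates a tape's sensitivity and specificity into the expected
#' screening outcome mix in a population with the given prevalence of
#' preterm-range pregnancies: the fraction classified positive and the
#' true/false positive and negative percentages. With sensitivity 77.7%,
#' specificity 88.6% and 20% prevalence — the working scenario for
#' community use among women presenting with emergency conditions — about
#' 25% of women screen positive (16% true preterm, 9% false positive) and
#' 75% screen negative (71% true term, 4% false negative).
#'
#' @param sens,spec,prevalence Proportions in `[0, 1]`.
#' @return A one-row tibble with `prevalence` and the five percentages
#'   (`classified_positive_pct`, `tp_pct`, `fp_pct`, `tn_pct`, `fn_pct`),
#'   unrounded; the four outcome percentages sum to 100.
#' @examples
#' predictive_projection(0.777, 0.886, 0.20)
#' @export
predictive_projection <- function(sens, spec, prevalence) {
  for (v in list(sens, spec, prevalence)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort("`sens`, `spec` and `prevalence` must be single proportions in [0, 1].")
    }
  }
  tp <- prevalence * sens
  fn <- prevalence * (1 - sens)
  fp <- (1 - prevalence) * (1 - spec)
  tn <- (1 - prevalence) * spec
  tibble(
    prevalence = prevalence,
    classified_positive_pct = 100 * (tp + fp),
    tp_pct = 100 * tp, fp_pct = 100 * fp,
    tn_pct = 100 * tn, fn_pct = 100 * fn
  )
}
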