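#' Build a tri-zone tape specification from a growth chart
#'
#' A tape partitions uterine height into three zones with gestational-age
#' semantics: low (expected GA < 24.0 weeks), mid (24.0-36.0 weeks, the
#' refer/treat zone) and high (> 36.0 weeks). The two boundaries are
#' percentile cut-offs read off a growth chart: the lower boundary is the
#' chosen percentile of UH at completed week 24, the upper boundary the
#' chosen percentile at week 36. The three study designs are `10-90`
#' (P10 at 24 w, P90 at 36 w — the widest mid zone), `50-50` (medians) and
#' `90-10` (P90 at 24 w, P10 at 36 w — the narrowest).
#'
#' Boundaries are stored at 0.1 cm resolution (tape printing granularity).
#'
#' @param chart A `uh_growth_chart` containing weeks 24 and 36.
#' @param lower_percentile,upper_percentile One of 10, 50, 90.
#' @return An object of class `uh_tape`: a list with `name`, `site`,
#'   `lower_cm`, `upper_cm`, `lower_percentile`, `upper_percentile`.
#' @examples
#' ph1 <- simulate_phase1(growth_model_params(), n_per_week = 50, seed = 1)
#' chart <- weekly_percentiles(ph1)
#' build_tape(chart, 10, 90)
#' @export
build_tape <- function(chart, lower_percentile, upper_percentile) {
  stopifnot(inherits(chart, "uh_growth_chart"))
  pcts <- c(10, 50, 90)
  if (!lower_percentile %in% pcts || !upper_percentile %in% pcts) {
    abort("percentiles must be one of 10, 50, 90.")
  }
  for (w in c(24L, 36L)) {
    if (!w %in% chart$week) abort(sprintf("chart must contain week %d.", w))
  }
  pick <- function(week, pct) {
    row <- chart[chart$week == week, ]
    round(row[[sprintf("p%d_cm", pct)]], 1)
  }
  lower_cm <- pick(24L, lower_percentile)
  upper_cm <- pick(36L, upper_percentile)
  name <- sprintf("%d-%d", lower_percentile, upper_percentile)
  if (lower_cm >= upper_cm) {
    abort(sprintf(
      "degenerate tape %s: lower boundary %.1f cm >= upper boundary %.1f cm",
      name, lower_cm, upper_cm))
  }
  structure(
    list(name = name, site = chart_site(chart),
         lower_cm = lower_cm, upper_cm = upper_cm,
         lower_percentile = as.integer(lower_percentile),
         upper_percentile = as.integer(upper_percentile)),
    class = "uh_tape"
  )
}

#' Construct a tape directly from its boundaries
#'
#' @param lower_cm,upper_cm Zone boundaries in cm (`lower_cm < upper_cm`);
#'   stored at 0.1 cm resolution.
#' @param name Tape label.
#' @param site Source chart label.
#' @param lower_percentile,upper_percentile Optional percentile provenance.
#' @return A `uh_tape` object.
#' @examples
#' tape_spec(20, 34)
#' @export
tape_spec <- function(lower_cm, upper_cm, name = "custom", site = "external",
                      lower_percentile = NA_integer_,
                      upper_percentile = NA_integer_) {
  lower_cm <- round(lower_cm, 1)
  upper_cm <- round(upper_cm, 1)
  if (!is.finite(lower_cm) || !is.finite(upper_cm) || lower_cm >= upper_cm) {
    abort("tape boundaries must satisfy lower_cm < upper_cm.")
  }
  structure(
    list(name = name, site = site, lower_cm = lower_cm, upper_cm = upper_cm,
         lower_percentile = as.integer(lower_percentile),
         upper_percentile = as.integer(upper_percentile)),
    class = "uh_tape"
  )
}

#' @export
print.uh_tape <- function(x, ...) {
  cat(sprintf("<uh_tape %s> (%s)\n", x$name, x$site))
  cat(sprintf("  low  (yellow, < 24.0 w): UH < %.1f cm\n", x$lower_cm))
  cat(sprintf("  mid  (red, 24.0-36.0 w): %.1f <= UH < %.1f cm\n",
              x$lower_cm, x$upper_cm))
  cat(sprintf("  high (green, > 36.0 w) : UH >= %.1f cm\n", x$upper_cm))
  invisible(x)
}

#' @rdname build_tape
#' @param x A `uh_tape` object.
#' @param ... Unused.
#' @method tidy uh_tape
#' @export
tidy.uh_tape <- function(x, ...) {
  tibble(name = x$name, site = x$site,
         lower_cm = x$lower_cm, upper_cm = x$upper_cm,
         lower_percentile = x$lower_percentile,
         upper_percentile = x$upper_percentile)
}

#' Classify a uterine-height measurement into a tape zone
#'
#' Measurements are rounded to 0.1 cm (the tape's printed granularity)
#' before comparison with the zone boundaries. Under the default
#' `"lower-closed"` convention each zone owns its left edge — the mid zone
#' is `[lower_cm, upper_cm)` — mirroring the half-open gestational-age bands,
#' so in the noise-free limit every gestational age maps to its intended
#' zone. The alternative `"mid-closed"` convention gives the shared upper
#' boundary to the mid (refer/treat) zone, the more conservative reading of
#' a color transition on a physical tape.
#'
#' @param tape A `uh_tape`.
#' @param uh Numeric vector of measurements in cm (> 0).
#' @param boundary Boundary convention, `"lower-closed"` (default) or
#'   `"mid-closed"`.
#' @return Factor with levels `low`, `mid`, `high`; every positive input
#'   maps to exactly one zone.
#' @examples
#' tape <- tape_spec(20, 34)
#' classify_uh(tape, c(19.9, 20, 33.9, 34, 34.2))
#' @export
classify_uh <- function(tape, uh, boundary = c("lower-closed", "mid-closed")) {
  stopifnot(inherits(tape, "uh_tape"))
  boundary <- match.arg(boundary)
  if (!is.numeric(uh) || anyNA(uh)) abort("`uh` must be numeric with no missing values.")
  if (any(uh <= 0)) abort("uterine height must be positive (cm).")
  u <- round(uh, 1)
  z <- if (boundary == "lower-closed") {
    ifelse(u < tape$lower_cm, "low", ifelse(u < tape$upper_cm, "mid", "high"))
  } else {
    ifelse(u < tape$lower_cm, "low", ifelse(u <= tape$upper_cm, "mid", "high"))
  }
  zone_factor(z)
}

#' Build the three standard tapes from one chart
#'
#' Returns the `10-90`, `50-50` and `90-10` designs. Because percentiles are
#' ordered within each week, the mid zones nest: `90-10`'s is contained in
#' `50-50`'s, which is contained in `10-90`'s. Fails if any design is
#' degenerate (possible for `90-10` when the chart is noisy enough that
#' P90 at 24 weeks reaches P10 at 36 weeks).
#'
#' @param chart A `uh_growth_chart` containing weeks 24 and 36.
#' @return Named list of three `uh_tape` objects (`10-90`, `50-50`, `90-10`).
#' @examples
#' ph1 <- simulate_phase1(growth_model_params(), n_per_week = 50, seed = 1)
#' build_standard_set(weekly_percentiles(ph1))
#' @export
build_standard_set <- function(chart) {
  combos <- list(`10-90` = c(10, 90), `50-50` = c(50, 50), `90-10` = c(90, 10))
  purrr::map(combos, ~ build_tape(chart, .x[1], .x[2]))
}

#' Serialize a tape specification to JSON
#'
#' @param tape A `uh_tape`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tape_json <- function(tape, path) {
  stopifnot(inherits(tape, "uh_tape"))
  jsonlite::write_json(unclass(tape), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tape_json
#' @export
read_tape_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tape_spec(x$lower_cm, x$upper_cm, name = x$name, site = x$site,
            lower_percentile = x$lower_percentile %||% NA_integer_,
            upper_percentile = x$upper_percentile %||% NA_integer_)
}
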