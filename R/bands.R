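# Gestational age is carried internally in days. Band edges follow the w.d
# convention: "35.6 weeks" means 35 completed weeks + 6 days = 251 days, so
# the three reporting bands are half-open intervals in days:
#   20.0-23.6 -> [140, 168), 24.0-35.6 -> [168, 252), 36.0-40.6 -> [252, 287).

GA_MIN_DAYS <- 140L
GA_MAX_DAYS <- 287L # exclusive: eligibility is 20.0-40.6 weeks

BAND_LEVELS <- c("20.0-23.6", "24.0-35.6", "36.0-40.6")
BAND_EDGES <- c(140L, 168L, 252L, 287L)

ZONE_LEVELS <- c("low", "mid", "high")
ZONE_COLORS <- c(low = "yellow", mid = "red", high = "green")

SITE_LEVELS <- c("Argentina", "Zambia", "India", "Pakistan")
TAPE_LEVELS <- c("10-90", "50-50", "90-10")
ENDPOINT_LEVELS <- c("24.0-35.6", "20.0-35.6")

#' Map gestational age in days to a reporting band
#'
#' Gestational age is recorded in days and grouped into the three reporting
#' bands used throughout the evaluation: early (`20.0-23.6` weeks, the
#' pre-viable range), preterm (`24.0-35.6` weeks, the antenatal-corticosteroid
#' window) and term (`36.0-40.6` weeks). Bands are half-open in days:
#' `[140, 168)`, `[168, 252)` and `[252, 287)`, reflecting the w.d notation in
#' which "35.6 weeks" is 35 weeks 6 days.
#'
#' @param ga_days Integer vector of gestational ages in days. All values must
#'   lie in the eligibility window `[140, 287)` days (20.0 to 40.6 weeks).
#' @return A factor with levels `"20.0-23.6"`, `"24.0-35.6"`, `"36.0-40.6"`.
#' @examples
#' ga_to_band(c(167, 168, 251, 252))
#' @export
ga_to_band <- function(ga_days) {
  if (!is.numeric(ga_days) || anyNA(ga_days)) {
    abort("`ga_days` must be numeric with no missing values.")
  }
  bad <- ga_days < GA_MIN_DAYS | ga_days >= GA_MAX_DAYS
  if (any(bad)) {
    abort(sprintf(
      "gestational age outside the eligibility window [%d, %d) days: %s",
      GA_MIN_DAYS, GA_MAX_DAYS,
      paste(utils::head(ga_days[bad], 5L), collapse = ", ")
    ))
  }
  cut(ga_days, breaks = BAND_EDGES, labels = BAND_LEVELS, right = FALSE)
}

#' Zone display colors
#'
#' The three tape zones are computed on under semantic names; the physical
#' tapes print them as colors: low (gestational age < 24.0 weeks) is yellow,
#' mid (24.0-36.0 weeks, the refer/treat zone) is red, high (> 36.0 weeks) is
#' green.
#'
#' @param zone Character or factor vector of zone names (`low`, `mid`, `high`).
#' @return Character vector of display colors.
#' @examples
#' zone_color(c("low", "mid", "high"))
#' @export
zone_color <- function(zone) {
  zone <- as.character(zone)
  bad <- !zone %in% ZONE_LEVELS
  if (any(bad)) abort(paste0("unknown zone: ", paste(unique(zone[bad]), collapse = ", ")))
  unname(ZONE_COLORS[zone])
}

zone_factor <- function(zone) factor(zone, levels = ZONE_LEVELS)
band_factor <- function(band) factor(band, levels = BAND_LEVELS)
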