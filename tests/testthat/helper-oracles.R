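# Independent area oracle: close the ROC polyline into a polygon with the
# right edge (1, tpr_last) -> (1, 0) -> (0, 0) and take the shoelace area.
# Shares no code with trapezoid_auc().
shoelace_auc <- function(fpr, tpr) {
  x <- c(fpr, 1, 0)
  y <- c(tpr, 0, 0)
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Two-week chart stub with chosen percentile anchors at weeks 24 and 36.
make_anchor_chart <- function(p24 = c(20, 22, 24), p36 = c(30, 32, 34),
                              site = "stub") {
  as_growth_chart(
    tibble::tibble(
      week = c(24L, 36L),
      n = 50L,
      mean_cm = c(p24[2], p36[2]),
      sd_cm = 1,
      p10_cm = c(p24[1], p36[1]),
      p50_cm = c(p24[2], p36[2]),
      p90_cm = c(p24[3], p36[3])
    ),
    site = site
  )
}

# Random valid zone-by-band cross-tab.
random_crosstab <- function(max_count = 60) {
  grid <- expand.grid(zone = c("low", "mid", "high"),
                      ga_band = c("20.0-23.6", "24.0-35.6", "36.0-40.6"),
                      stringsAsFactors = FALSE)
  grid$count <- sample.int(max_count, 9L, replace = TRUE)
  as_crosstab(grid, site = "random", tape = "custom")
}

fixture_sites <- c("Argentina", "Zambia", "India", "Pakistan")
fixture_tapes <- c("10-90", "50-50", "90-10")

site_tabs <- function(site) lapply(fixture_tapes, load_fixture, site = site)
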