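#' Recompute the published accuracy results from the embedded cross-tabs
#'
#' Runs the whole accuracy pipeline on the embedded fixtures: all 48
#' sensitivity/specificity point estimates (4 sites x 3 tapes x 2
#' endpoints), the eight site-level trapezoidal AUCs, the spot-check Wald
#' confidence intervals, and the prevalence projection, each compared
#' against the published value at its printed rounding (percent to 1
#' decimal, AUC to 2 decimals, projection to integer percent).
#'
#' Three of the eight published AUCs (Zambia at both endpoints, Pakistan at
#' 20.0-35.6 weeks) are not recoverable from the printed cross-tabs: the
#' published values differ by 0.01-0.02 from the trapezoidal area over the
#' per-tape operating points. Each woman was measured with all three tapes,
#' and an ROC computed from those individual-level joint records need not
#' coincide with one computed from the per-tape marginal tables, which are
#' all that was printed. The five remaining AUCs and all 48
#' sensitivity/specificity cells reproduce exactly at printed rounding.
#'
#' @param ci_method Interval method passed to [sens_spec()].
#' @return A tibble of class `uh_reproduction` with columns `quantity`,
#'   `site`, `tape`, `endpoint`, `computed`, `published`, `match` (agreement
#'   at printed rounding), plus `ci_low`/`ci_high` comparisons for the spot
#'   cells.
#' @examples
#' rep <- reproduce_published()
#' dplyr::count(rep, quantity, match)
#' @export
reproduce_published <- function(ci_method = "wald") {
  v <- validate_fixtures()
  if (!all(v$ok)) abort("embedded fixtures failed validation; see validate_fixtures().")
  tabs <- purrr::map(
    setNames(SITE_LEVELS, SITE_LEVELS),
    function(s) purrr::map(setNames(TAPE_LEVELS, TAPE_LEVELS),
                           function(tp) load_fixture(s, tp))
  )
  acc <- purrr::map_dfr(tabs, function(site_tabs) {
    purrr::map_dfr(site_tabs, tape_accuracy, method = ci_method)
  })
  pub <- published_accuracy()
  cells <- acc |>
    dplyr::mutate(computed = 100 * .data$estimate) |>
    dplyr::inner_join(dplyr::filter(pub, .data$kind != "auc"),
                      by = c("site", "tape", "endpoint", "kind")) |>
    dplyr::transmute(
      quantity = .data$kind, site = .data$site, tape = .data$tape,
      endpoint = .data$endpoint, computed = .data$computed,
      published = .data$published,
      match = abs(.data$computed - .data$published) <= 0.05 + 1e-9
    )
  rocs <- purrr::map_dfr(ENDPOINT_LEVELS, function(ep) {
    purrr::map_dfr(SITE_LEVELS, function(s) {
      glance(roc_curve(unname(tabs[[s]]), ep))
    })
  })
  auc_rows <- rocs |>
    dplyr::inner_join(dplyr::filter(pub, .data$kind == "auc"),
                      by = c("site", "endpoint")) |>
    dplyr::transmute(
      quantity = "auc", site = .data$site, tape = NA_character_,
      endpoint = .data$endpoint, computed = .data$auc,
      published = .data$published,
      match = abs(.data$computed - .data$published) <= 0.005 + 1e-9
    )
  ci_rows <- published_ci_spots() |>
    purrr::pmap_dfr(function(site, tape, endpoint, kind, ci_low, ci_high) {
      est <- sens_spec(dichotomize(load_fixture(site, tape), endpoint),
                       method = ci_method)
      est <- est[est$kind == kind, ]
      tibble(
        quantity = c(paste0(kind, "_ci_low"), paste0(kind, "_ci_high")),
        site = site, tape = tape, endpoint = endpoint,
        computed = 100 * c(est$ci_low, est$ci_high),
        published = c(ci_low, ci_high),
        match = abs(computed - published) <= 0.05 + 1e-9
      )
    })
  scen <- published_projection()
  proj <- predictive_projection(scen$sens, scen$spec, scen$prevalence)
  proj_rows <- tibble(
    quantity = paste0("projection_", c("classified_positive", "tp", "fp", "tn", "fn")),
    site = "India", tape = "90-10", endpoint = "20.0-35.6",
    computed = c(proj$classified_positive_pct, proj$tp_pct, proj$fp_pct,
                 proj$tn_pct, proj$fn_pct),
    published = c(scen$classified_positive_pct, scen$tp_pct, scen$fp_pct,
                  scen$tn_pct, scen$fn_pct),
    match = round(computed) == published
  )
  out <- dplyr::bind_rows(cells, auc_rows, ci_rows, proj_rows)
  structure(out, class = c("uh_reproduction", class(tibble())))
}

#' @export
print.uh_reproduction <- function(x, ...) {
  needed <- c("quantity", "site", "tape", "endpoint", "computed", "published", "match")
  if (!all(needed %in% names(x))) return(NextMethod())
  n_bad <- sum(!x$match)
  cat(sprintf("<uh_reproduction> %d quantities recomputed, %d mismatching\n",
              nrow(x), n_bad))
  if (n_bad > 0) {
    bad <- x[!x$match, ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  MISMATCH %s [%s %s %s]: computed %.4f vs published %.4g\n",
                  bad$quantity[i], bad$site[i],
                  ifelse(is.na(bad$tape[i]), "-", bad$tape[i]),
                  bad$endpoint[i], bad$computed[i], bad$published[i]))
    }
  }
  NextMethod()
}
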