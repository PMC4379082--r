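---
title: "Designing and evaluating color-coded uterine-height tapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating color-coded uterine-height tapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhtape)
```

## The problem and the instrument

Antenatal corticosteroids reduce neonatal mortality when given to women
at risk of preterm birth, but they require knowing that a pregnancy is
in roughly the 24–36 week window. Where ultrasound dating is
unavailable and providers may not read or write, a tri-zone measuring
tape offers a workable proxy: uterine height (symphysis-fundal height)
grows approximately linearly with gestational age at about 1 cm per
week, so a measured length can be mapped to a color — yellow for an
expected GA below 24.0 weeks, red for 24.0–36.0 weeks (the refer/treat
zone), green for above 36.0 weeks.

This package implements the whole design-and-evaluate workflow as
composable, data-frame-first functions, and embeds the cross-tabulated
results of a published four-country evaluation so that the accuracy
analysis is reproducible offline.

## The measurement and growth model

Phase-1 (calibration) data are paired readings: two operators measure
the same woman independently. The package models a woman at completed
week $w$ as

$$UH_{ij} = \beta_0 + \beta_1 w_i + b_i + e_{ij}, \qquad
b_i \sim N(0, \sigma_b^2),\; e_{ij} \sim N(0, \sigma_o^2),$$

where $b_i$ is a stable woman-level deviation and $e_{ij}$ independent
operator error. Agreement between the operators is summarised the
standard Bland–Altman way: bias $\bar d$, SD of the differences $s_d$,
and 95% limits of agreement $\bar d \pm 1.96 s_d$. Since
$d \sim N(0, 2\sigma_o^2)$ under the model, the default
$\sigma_o = 0.9$ cm puts the limits at $1.96\sqrt{2}\cdot 0.9 \approx
2.5$ cm — inside the 2–3 cm band reported for the calibration phase,
which is what motivated using the mean of the two readings per woman.

Default generator parameters ($\beta_0 = 1.0$ cm, $\beta_1 = 0.9$
cm/week, $\sigma_b = 2.0$ cm, $\sigma_o = 0.9$ cm) were chosen once for
clinical plausibility: UH ≈ 22.6 cm at 24 weeks and ≈ 33.4 cm at 36
weeks, a few cm of between-woman spread, and the agreement band above.
They are the package's standing study conditions, not tuning knobs.

## Growth charts and tape construction

Per-week charts summarise the per-woman mean UH for each completed week
24–36: n, mean, SD, P10, P50, P90. Quantiles use linear interpolation
between order statistics (R's default type 7); the choice is exposed
because percentile charts at 30–50 women per week are sensitive to the
estimator, and no single convention is universal.

A tape is two cut-offs read off the chart: the lower boundary is a
percentile of UH at week 24, the upper a percentile at week 36. The
three standard designs — `10-90`, `50-50`, `90-10` — trade sensitivity
for specificity: `10-90` has the widest red zone (hardest to miss a
preterm-range pregnancy, most false alarms), `90-10` the narrowest.
Because P10 ≤ P50 ≤ P90 within each anchor week, the red zones nest,
which in turn guarantees the monotone ordering of sensitivity (and the
reverse ordering of specificity) across designs for the red-zone
endpoint. A `90-10` tape can be degenerate if the chart is noisy enough
that P90 at 24 weeks reaches P10 at 36 weeks; this is rejected with an
explicit error.

Boundaries are stored at 0.1 cm — the resolution at which a physical
tape can be printed — and measurements are rounded to 0.1 cm before
classification.

### Boundary convention

Gestational-age bands are half-open in days: with "35.6" read as 35
weeks 6 days, the bands are $[140, 168)$, $[168, 252)$ and $[252, 287)$
days. The zone boundaries mirror this: by default each zone owns its
left edge, so the red zone is $[\ell, u)$ in cm. The alternative
reading — a color transition belongs to the red zone on both sides
(`boundary = "mid-closed"`), the clinically conservative choice at the
upper edge — is available as an option. The half-open default was
chosen because it makes the deterministic limit exact: with all noise
at zero, a woman at exactly 36.0 weeks measures exactly the upper
boundary, and the half-open convention classifies her green, in
agreement with her term band; the closed convention would flag her red.
The two conventions can only differ for measurements landing exactly on
a boundary after rounding, and the choice has no effect on fixture-based
results, which are pre-classified counts.

## Evaluation: endpoints, intervals, ROC

The evaluation phase samples a fixed GA distribution per site (default
plan: 50 women at 20.0–23.6 weeks; 10, 20 and 70 across the preterm
strata 24.0–27.6, 28.0–31.6, 32.0–35.6; 100 at 36.0–40.6; 250 total),
with GA uniform at day resolution within each stratum — the plan fixes
only stratum counts, so uniformity is the least-informative choice.
Each woman contributes one masked reading with combined noise
$\sqrt{\sigma_b^2 + \sigma_o^2}$.

Zone-by-band cross-tabs are reduced to binary tests two ways: red
positive for the 24.0–35.6-week endpoint; red-or-yellow positive for
20.0–35.6 weeks. Sensitivity and specificity use each tape's own
denominators (tapes can have missing readings independently — the
embedded Argentina `50-50` table has 106 rather than 107 term-band
measurements). Intervals are Wald by default,
$p \pm 1.96\sqrt{p(1-p)/n}$, because that is the method the published
intervals follow (verified on several cells, e.g. 87.0 → (82.1, 92.0)
at $n = 177$); they are clipped to $[0,1]$ unless asked otherwise, and
Clopper–Pearson is available. The ROC per site connects the three
per-tape operating points $(1-Sp, Se)$, augmented with $(0,0)$ and
$(1,1)$ and sorted by false-positive rate; the AUC is the trapezoidal
area. The AUC interval uses the Hanley–McNeil standard error with the
average case/non-case counts across tapes; it is indicative only and
deliberately excluded from the reproduction surface, since the original
interval method is unstated.

The prevalence projection is plain algebra at a working prevalence
$\pi$: the positive fraction is $\pi\,Se + (1-\pi)(1-Sp)$, decomposed
into true/false positives and negatives; percentages are reported
unrounded (they sum to 100 exactly) and rounded only for display.

## The embedded fixtures and zone orientation

The published cross-tabs (4 sites × 3 tapes × 3 zones × 3 GA bands)
ship as a plain CSV under `inst/extdata/` with semantic zone labels
`low`/`mid`/`high`. One transcription issue had to be resolved: taken
verbatim, the published yellow and green row labels are inconsistent
with the published accuracy table — for example the Argentina `10-90`
table would give a 20.0–35.6-week specificity of 0/107, where 29.9%
(= 32/107) was published. Interchanging the yellow and green row
assignments reproduces every published sensitivity and specificity cell
at printed rounding; the red row is unaffected. The fixtures therefore
store the interchanged orientation, the loader documents it, and no
computation relies on color names. Whether the inconsistency is a
typesetting artifact of the zone rows or of the row labels cannot be
decided from the printed tables alone; the interchange is adopted
because it makes the published tables mutually consistent under the
stated decision rules.

`validate_fixtures()` asserts all margins against the published
enrollment (284/242/253/250 women; 1,029 total) with the single
documented denominator exception, and `reproduce_published()` reruns
the full accuracy surface against the published values.

### What the marginals cannot reproduce

Each woman was measured with all three tapes, and the original ROC
analysis was run on those individual-level records. The printed tables
are per-tape *marginals*: the joint distribution of a woman's three
readings is not recoverable from them. Empirically, the trapezoid over
the marginal operating points reproduces five of the eight published
AUCs at two decimals (Argentina 0.64/0.69, India 0.71/0.84, Pakistan
0.72 for 24.0–35.6 weeks); Zambia's two AUCs and Pakistan's
20.0–35.6-week AUC differ by 0.005–0.017 (e.g. 0.637 recomputed vs 0.65
published). The package reports the recomputed values and flags the
three discrepant cells in `reproduce_published()`; it does not adjust
anything to force agreement. Published AUC *confidence intervals* are
excluded from reproduction altogether (method unstated), as are the
per-week percentile values of the deployed tapes and the original
sample-size interval, none of which are recoverable from the available
text.

## What the synthetic generator does and does not emulate

It reproduces the statistical structure the analysis assumes: linear
mean growth, normal between-woman and operator variation, the
two-operator calibration design, the stratified evaluation plan with
exact stratum counts, and full determinism under a seed (both phases
derive their streams from one seed; the evaluation phase offsets it so
the two cohorts are independent). It does not emulate: non-linear
growth near term, regional anthropometric differences (the two deployed
tape families are simply different charts in, different tapes out),
complication-induced UH reduction (rupture of membranes, preeclampsia
with growth restriction), operator drift, or digit preference. Passing
simulation tests therefore demonstrate internal consistency of the
pipeline under its own assumptions, not field performance of a physical
tape.

## Numerical choices and problem sizes

Tolerance and size choices used by the test suite, stated here as the
package's own: agreement and percentile-recovery checks run at 1,000
women per week (median recovered within ±0.3 cm, about four standard
errors of the weekly median under the default spread); Monte-Carlo
fraction checks at 500 women per week against the closed-form normal
oracle; ordering and conservation properties on all twelve fixtures and
on one simulated run of the default 250-woman plan. The
published-table reproduction itself is exact arithmetic on embedded
counts and runs in well under a second.

Degenerate inputs are errors, not warnings: empty cohorts, weeks with
fewer than two women (named in the message), non-positive measurements,
zero case or non-case margins, degenerate tapes. Missing UH readings
are excluded and counted, never imputed; a missing reading in a
calibration *pair* is an error because the pair is the unit of
agreement.

## Limitations

Beyond the AUC marginals issue above: the Wald interval is known to
undercover for extreme proportions (one published upper bound exceeds
100%, which clipping addresses at the cost of exact agreement with that
printed cell); the empirical ROC over three points is a coarse summary
and its trapezoid underestimates any smooth curve through the same
points; and the evaluation design's case-enriched sampling (60%
preterm-range) means predictive values in the field require the
prevalence projection, not the raw cross-tabs.
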