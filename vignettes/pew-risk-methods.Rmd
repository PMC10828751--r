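---
title: "Methods: scoring, stratification and validation of the hemodialysis PEW risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, stratification and validation of the hemodialysis PEW risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pewrisk)
```

## The instrument

Protein-energy wasting (PEW) -- depletion of protein and energy stores in
chronic kidney disease -- is common in maintenance hemodialysis patients
and is associated with hospitalization and death. Hashmi's tool is a
six-component screening score built entirely from measurements already
collected in routine dialysis care. Each component is banded into four
ordinal severity levels worth 0-3 points:

| Component | 0 | 1 | 2 | 3 |
|---|---|---|---|---|
| BMI (kg/m²) | ≥ 20 | 18-19.9 | 16-17.9 | < 16 |
| Functional capacity | normal | occasional difficulty | difficulty in independent activities | bed/chair-bound |
| HD vintage (years) | < 1 | 1 to < 3 | 3-4 | > 4 |
| Serum albumin (g/L) | ≥ 35 | 32-35 | 28-31 | < 28 |
| Serum ferritin (µg/L) | < 700 | 701-800 | 801-1000 | > 1000 |
| Comorbidity count | 1 | 2 | 3 | > 3 |

The total runs from 0 to 18 and is dichotomized at a threshold of 6:
total < 6 is *low risk*, total ≥ 6 is *high risk*. Comorbidities counted
are diabetes mellitus, hypertension, ischemic heart disease and
cerebrovascular disease.

### Band-edge conventions

The printed grid leaves gaps (e.g. 19.9 vs 20, 31 vs 32, 700 vs 701,
800 vs 801) and one overlap (albumin 35 appears in both "≥ 35" and
"32-35"). The package closes these once, as a documented convention, so
every positive value maps to exactly one band:

* For BMI and albumin (low = severe) a boundary value belongs to the
  *less severe* band: BMI 20 scores 0, albumin 35 scores 0, albumin 32
  scores 1; band 2 extends to `[28, 32)`.
* For ferritin (high = severe) a boundary belongs to the *lower* band:
  700 scores 0, 700.5 scores 1, 800 scores 1, 1000 scores 2.
* Vintage exactly 3 years scores 2 and exactly 4 years scores 2: the
  "3-4 years" band is read as closed at both ends because "1 to < 3"
  excludes 3 and "> 4" excludes 4.
* Zero comorbidities scores 0 (below the least severe printed band; the
  score cannot be negative).

Only the cut *positions* can be overridden (via `read_bands()` and a
YAML file, or the `cuts` arguments); the open/closed side of each cut is
part of the instrument's definition here and is fixed. Missing scoring
inputs raise an error naming the field -- a screening score silently
computed on partial data would be unsafe.

### Quarterly aggregation

The score is recorded quarterly but outcomes are compared per patient.
Which quarterly score stratifies a patient is genuinely open; the
package defaults to the **maximum** across quarters (the most
conservative choice for a screening instrument -- a patient flagged in
any quarter stays flagged) and also offers `baseline`, `latest` and
`mean_rounded` policies through `aggregate_quarters()`. Under
`mean_rounded` the components are averaged and rounded half-up
individually and the total is re-summed, preserving the invariant that
the total equals the sum of the components.

## Validation statistics

The validation design is deliberately simple: stratify the cohort at
threshold 6, then cross-tabulate each demographic/clinical factor and
each outcome against the risk group.

* **Odds ratio**: the cross-product `(a*d)/(b*c)` of the 2×2 table with
  the reference level in the first row.
* **Confidence interval**: the Woolf (log) interval,
  `exp(log(OR) ± z · sqrt(1/a + 1/b + 1/c + 1/d))`. The original
  validation report does not name its interval method; Woolf was adopted
  because it reproduces every published interval to the printed two
  decimals (e.g. gender 1.34-2.30, ischemic heart disease 3.56-6.55).
  With any zero cell the estimate is a hard error by default; the
  Haldane-Anscombe +0.5 correction is opt-in (`haldane = TRUE`), never
  silent, because silent corrections change published-style estimates.
* **Chi-square**: the uncorrected Pearson statistic (Yates correction
  off by default, available via `correct = TRUE`), with the upper-tail
  p-value. Three-level factors (marital status) get an r×k chi-square
  and no odds ratio.
* **Row percentages**: each exposure row as percent low vs percent high
  risk, the presentation used in the published tables.

Report rounding follows the published style: odds ratios to 3 decimals,
confidence limits to 2, percentages to 1. Internally everything is kept
at full precision; rounding happens only at render time.

### Known non-reproduction

The packaged mortality table is derived from the published death counts
(31 of 429 low-risk, 92 of 439 high-risk patients died), giving

```{r}
fx <- load_fixture_tables()
odds_ratio(fx$mortality)
```

whereas the published table prints 3.388 (about 0.5% away). The counts
are the primary source, so the package reports the counts-derived value
and carries the published figure only as fixture metadata; rendered
reports footnote the difference rather than reconciling it. Similarly,
the running text gives the ischemic-heart-disease odds ratio as 4.38 in
one place; the value the counts reproduce is 4.830, which is what the
fixture carries. Absolute admission counts were never published (only
percentages), so no admission fixture tables exist and admission
statistics are computed only on patient-level data.

## The synthetic cohort generator

No patient-level data are distributed with the instrument, so the
package generates cohorts that match the validation cohort's *published
marginals* (defaults of `simulation_config()`): n = 868; age
59.6 ± 15.57 y truncated to the observed 19-103 range; hemoglobin
113.6 ± 11.99 g/L; Kt/V 1.7 ± 0.49; 467/868 male; marital mix
680/100/88; 660/868 on erythropoietin; and per-component band
frequencies taken from the published counts (e.g. 786/868 in the best
BMI band, 628/868 with vintage > 4 y, functional capacity
331/196/165/176, comorbidity count 189/278/258/143). Where only the
best band's frequency was published, the residual mass is split evenly
over the remaining three bands (config-overridable).

Modelling choices a user should know about:

* **Independence.** Components are drawn independently; the joint
  distribution of the real cohort was never published, and independence
  is the minimal assumption. Correlated components (e.g.
  albumin-functional capacity coupling in true PEW) are *not* emulated,
  so passing simulation tests demonstrates calibration of the pipeline,
  not realism of any particular joint structure.
* **Uniform within band.** Continuous values are drawn uniformly inside
  each band's numeric interval, truncated at physiologic limits for the
  open-ended bands (BMI 12-45 kg/m², vintage 0-25 y, albumin 15-50 g/L,
  ferritin 10-3000 µg/L; all config-exposed). Within-band distributions
  in the real cohort are unreported; uniformity is a declared choice,
  not an inference.
* **Comorbidity mix.** The count (1-4) comes from the published band
  frequencies; *which* conditions are present is a weighted sample
  without replacement with weights roughly proportional to published
  prevalences (hypertension 84%, diabetes 54%, IHD ≈ 36%, CVD assumed
  20%).
* **Outcomes.** Each outcome is Bernoulli with
  `logit(p) = intercept + slope × total score` -- logistic in the total,
  not in components, because the validation design is entirely
  score-mediated. Default coefficients were calibrated analytically from
  the published group-specific event rates: death (-3.96, 0.34),
  vascular admission (-0.77, 0.08), non-vascular admission
  (-1.21, 0.27). The implied high-vs-low odds ratios under the default
  marginals can be computed exactly (no simulation) because the total
  score's distribution is the convolution of six independent 4-point
  distributions:

```{r}
implied_odds_ratio(simulation_config(), "died")
implied_odds_ratio(simulation_config(), "adm_vascular")
implied_odds_ratio(simulation_config(), "adm_nonvascular")
```

`recover_association()` closes the loop: it repeatedly generates a
cohort, runs scoring → stratification → contingency analysis, and
compares the distribution of estimated odds ratios with the implied
value. Replicates that collapse into a single risk group are flagged and
excluded with their count reported; a replicate with a zero event cell
is estimated with the Haldane-Anscombe correction and marked.

## Numerical and testing choices

* Chi-square statistics are delegated to `stats::chisq.test()` behind
  the package's interface; the test suite checks them against an
  independent brute-force `sum((O-E)^2/E)` oracle on a thousand random
  tables, and chi-square p-values against numerical integration of the
  chi-square density.
* Calibration checks use moderate problem sizes chosen to keep the
  default test run quick while leaving Monte-Carlo error well inside the
  asserted bands: 200 replicate cohorts of n = 868 for the null
  rejection rate (expected ≈ 5%), 10,000 sampled tables at a true odds
  ratio of 2.5 for Woolf coverage (expected ≈ 95%), 100-200 replicates
  for association recovery. All seeds are fixed literals.
* `simulate_cohort()` draws random numbers in a fixed documented order,
  so a config plus seed reproduces a cohort byte-for-byte through
  `write_cohort()`.
* Degenerate inputs fail loudly and specifically: zero cells name the
  cell, all-zero rows/columns are "degenerate table" errors, cohort rows
  violating the data dictionary are collected into a rejection report
  (or abort under `strict = TRUE`), and no record is ever dropped
  silently.

## Limitations

* The generator reproduces marginals, not the joint distribution, so
  simulated factor-vs-risk odds ratios (e.g. for sex) will hover near 1
  unless the user injects the association; only the score-outcome
  channel is modelled.
* The scoring grid's boundary conventions are a reading of a printed
  table with gaps; a clinic applying different tie-breaking at band
  edges could score a handful of borderline patients one point apart.
* The pipeline pools centers (as the validation did); `center` is
  carried through as an optional column but never modelled.
* Admissions are counted as patients with ≥ 1 admission of a type, not
  as admission events; event-count data were not published.
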