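---
title: "Methods: from monthly precipitation to crop-drought sensitivity and its determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from monthly precipitation to crop-drought sensitivity and its determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

droughtsens estimates, for every cell of a regular latitude–longitude grid,
how strongly annual crop yields respond to meteorological drought, and then
asks which physical and socioeconomic properties of a place explain the
spatial pattern of that response. This vignette is the package's account of
the method: the model at each stage, its assumptions, the knobs that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## The drought index

Drought is measured by the Standardized Precipitation Index (SPI). Monthly
precipitation is accumulated over a k-month window (default **k = 9**
months, a scale long enough to reflect persistent precipitation deficit
rather than single dry months; `accumulate_precip()`). For each cell and
calendar month, the accumulations across years are fitted with a gamma
distribution and mapped through the fitted CDF and the standard-normal
quantile function (`compute_spi()`), so SPI has mean ≈ 0 and sd ≈ 1 over the
calibration window by construction. The calibration window defaults to the
full analysis window (1981–2016 in the standard configuration).

Numerical choices, all exposed but deliberately defaulted:

* **Gamma estimation** uses Thom's closed-form approximation on the strictly
  positive accumulations: with `A = log(mean) − mean(log x)`,
  `shape = (1 + sqrt(1 + 4A/3))/(4A)` and `scale = mean/shape`. It is the
  standard SPI estimator, has no convergence failures, and at n = 36 years
  its finite-sample error is well inside the calibration tolerances the
  tests enforce (|mean| < 0.05, |sd − 1| < 0.15 per cell-month). Maximum
  likelihood would be an acceptable drop-in; the tests check the
  distributional behaviour, not the estimator's identity.
* **Dry months.** Exact zeros get a point mass: `H(x) = q + (1 − q) G(x)`
  for x > 0 and `H(0) = q/2`, with q the observed zero fraction. Without
  this, arid cells with zero-inflated accumulations cannot be standardized.
* **Degenerate fits** — fewer than 3 positive values, or zero
  log-dispersion — are flagged and propagate missing SPI rather than
  fabricated values.
* **Clipping.** SPI is clipped to ±3.09 (the normal 0.001/0.999 quantiles)
  so empirical tail excursions never produce infinite deviates.
* **Ensembles.** When several precipitation products are supplied, SPI is
  computed per product and then averaged cell-month-wise
  (`ensemble_spi()`); averaging happens on the standardized index, not on
  raw precipitation, because products are correlated estimates of the same
  signal and the index is what downstream stages consume.

The annual **drought index** DI is the magnitude of negative SPI at each
cell's harvest month (a static crop-calendar raster applied to every year):
`DI = −SPI` when SPI < 0 and null otherwise (`compute_di()`). DI is
non-negative where defined and undefined in non-drought years; the boundary
SPI = 0 belongs to the null branch.

## Yield anomalies

Expected yield is a smooth trend fitted per cell by locally weighted
polynomial regression of yield on year (tricube weights; `fit_yield_trend()`
wraps `stats::loess` with `surface = "direct"` so an exactly affine series
is reproduced to machine precision). The anomaly is the percent deviation
`ΔY = (Y − Ȳ)/Ȳ × 100` (`anomaly_percent()`).

The bandwidth and degree are genuinely open choices: defaults are
**span = 0.67** and **degree = 2**, common local-polynomial settings that
track multi-decadal technology trends without chasing inter-annual noise in
a 36-year record. Both are configuration knobs, and the package's recovery
tests use tolerance bands wide enough that nearby choices behave the same.
Edge years are fitted with the asymmetric neighbourhoods the truncated
weight window implies; no extrapolation beyond observed years is done.
Cell-years with a non-positive fitted trend are disqualified (missing
anomaly, counted in a warning) instead of producing explosive percentages,
and cells with fewer than `max(4, degree + 2)` finite years are flagged
untrendable.

## Sensitivity

Per cell, sensitivity is the ordinary-least-squares slope β of
`ΔY = a + β · DI` with a classical two-tailed t-test on the slope
(`fit_sensitivity()`, `sensitivity_map()`); significance is P < 0.05 with no
multiple-testing correction, keeping each cell's test interpretable on its
own. β is in percent yield change per unit drought index, so negative β is
drought-induced loss.

Because DI is *null* (not zero) in non-drought years, there is a real fork
in how the regression sample is formed. The package's default,
`di_policy = "drop"`, reads nullity as exclusion: only drought years enter,
and at least `n_min = 10` of them are required (cells failing this are
flagged, not silently dropped). The alternative reading,
`di_policy = "zero"`, enters non-drought years at DI = 0 and is preserved
behind the same interface; when the harvest-month SPI accompanies the DI
series the policy still distinguishes "non-drought" from "SPI missing".
`n_min = 10` balances estimator stability (8 residual degrees of freedom)
against coverage in a 36-year record where roughly half the years are
drought years.

Downstream summaries (`summarize_sensitivity()`) report the share of
evaluated cells that are significant, the share of significant cells that
are negative, and mean β over all and over significant cells — each both
unweighted and harvested-area-weighted, because the appropriate weighting
depends on whether one asks about places or about production.
`classify_irrigation()` splits cells at a strictly-greater-than **0.8**
irrigated fraction (0.80 itself is rainfed), and `binned_area_share()`
histograms harvested area over half-open β bins `[lo, hi)` of width
**5 %/DI** anchored so 0 is a bin edge; shares are normalized to 100% within
each irrigation class.

## Attribution

The spatial pattern of β is regressed on 22 determinant rasters spanning
climate, terrain, soil, irrigation, production, fertilizer and
socioeconomic classes (`determinant_names()`), using a random forest with
**500 trees** and otherwise default hyperparameters
(`fit_attribution()`; the forest's task is ranking and shape recovery, not
squeezing out the last point of R²). Every cell with a finite β and
complete predictors enters — no significance filter — since filtering on the
response would bias the attribution sample; rows with any missing predictor
are dropped and counted by cause (`build_feature_table()`).

Skill is reported as out-of-bag R² and RMSE: each cell is predicted only by
trees whose bootstrap excluded it, an internal validation that needs no
held-out set. Importance is impurity (node-variance-reduction) importance,
reported three ways: raw, share-normalized (sums to 1), and min–max
normalized to [0, 1] — the last computed per crop, which is the convention
used when comparing importance profiles across crops. Ranks break ties by
fixed column order so ranked tables are deterministic. Partial dependence
(`partial_dependence()`) forces one predictor across an equally spaced grid
between its 1st and 99th percentile — trimmed to avoid extrapolation
artifacts in the tails — and averages predictions over all training rows.
Alternative learners can be benchmarked by fitting any model with the same
feature table and comparing importance rankings externally; the package
deliberately ships only the forest.

## What the synthetic generator emulates — and what it does not

Every pipeline input can be generated with known ground truth
(`simulate_precipitation()`, `simulate_crop_calendar()`,
`simulate_yields()`, `simulate_predictors()`), so every stage has a
recovery test:

* Precipitation is drawn from the same mixed gamma family the SPI fit
  assumes (per-calendar-month shape/scale, a zero-rain mass, default 5%),
  with ensemble members sharing a latent draw plus independent truncated
  noise so members correlate like real products. Defaults give a mild
  seasonal cycle around ~75 mm/month.
* Yields are a positive smooth trend (linear/logistic/piecewise; default
  5 t/ha plus 0.05 t/ha yr⁻¹) perturbed multiplicatively by a planted β
  times DI plus Gaussian noise (default σ = 3%), with DI treated as 0 in
  non-drought years — the same convention the analysis side uses, which is
  what makes recovery tests meaningful.
* Predictors are spatially smooth standardized Gaussian random fields
  (white noise blurred at a 3-cell scale — enough spatial autocorrelation
  to be realistic without long-range degeneracy). The true β field is
  `β₀ + Σ link_j(x_j) + η` with defaults β₀ = −8, two active links
  (precipitation, linear, +5 per sd; water-holding capacity, saturating
  tanh, amplitude 4) and twenty pure-noise controls, η with sd 2.

The generator reproduces the *statistical structure* the method assumes; it
does not reproduce real-world spatial patterns, storm persistence,
spatially correlated yield shocks, measurement error in yield datasets, or
the mixing of irrigated and rainfed production within a cell. Passing tests
therefore demonstrate that the machinery is correct and calibrated under
the stated model — not that any particular real-world number is right.

## The exactness chain and its one concession

With noise switched off (σ = 0) and the true trend known, the whole chain
SPI → DI → anomaly → OLS recovers a planted heterogeneous β field to below
10⁻⁸ (the tests observe ~10⁻¹⁴). One design point deserves honesty: a
*smoothed* trend cannot participate in that exactness chain. When drought
perturbations are present, any smoother's trend estimate absorbs part of
the perturbation, so anomalies computed against a loess trend differ from
the planted ones at the percent level, not at machine precision. The
numerical-exactness test therefore conditions on the generator's known
trend (`anomaly_percent(..., trend_col = "trend_true")`, or
`trend_method = "known"` in the pipeline config), isolating the
drought-regression machinery; the loess path is validated separately and
statistically — unbiasedness and 95% CI coverage of β̂ under noise, and
median recovery of a planted β through the full loess pipeline. In the full
pipeline run the loess path's CI coverage sits slightly below nominal
(the trend-estimation error the chain conditions away), which is the
expected price of estimating the trend from the same series.

## Problem sizes and runtime posture

The package targets desk-scale grids. The shipped tests and the acceptance
script use a 20 × 20 grid of 0.5° cells over 36 years for the SPI and
recovery chains, a 10⁴-month single-cell series for the
quantile-equivalence check, 1000–2000 simulated cells for the type-I-error
and coverage experiments, and a 45 × 45 grid (2025 cells) with 20 seeded
repetitions for attribution-rank recovery — sizes chosen so the full suite
exercises every claim in minutes on one CPU while keeping Monte-Carlo
bands tight (a binomial 99% band around a 5% type-I rate at n = 2000 is
roughly ±1.5 points). Nothing in the method is specific to these sizes;
`pipeline_config()` scales the same code to larger grids.

## Known limitations

* Drought is precipitation-only. Temperature-driven evaporative demand,
  soil moisture, and compound heat–drought events are outside the index.
* One harvest month per cell, fixed across years; multi-season cropping and
  calendar shifts are not represented.
* The per-cell regression is linear; threshold or saturating yield
  responses appear only through the attribution stage's nonlinear links.
* No spatial autocorrelation correction in the per-cell tests, and no
  field-significance adjustment — each cell's P value is marginal.
* Impurity importance is known to favour high-variance continuous
  predictors; with all predictors standardized smooth fields this bias is
  mild, but rankings on real heterogeneous rasters should be read with it
  in mind.
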