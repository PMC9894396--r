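# droughtsens

Quantify how strongly crop yields respond to meteorological drought, cell
by cell on a regular latitude–longitude grid, and attribute the spatial
pattern of that response to physical and socioeconomic determinants.

The package is aimed at agro-climatologists and crop–climate analysts who
work with gridded monthly precipitation, gridded annual yields, a crop
calendar, and static determinant rasters (soil, terrain, irrigation,
fertilizer, socioeconomic). Everything is tidyverse-native: functions take
tibbles and return tibbles, so stages chain with the pipe; gridded
artifacts read and write CF-style NetCDF.

## The method

1. **Drought index.** Monthly precipitation is accumulated over k months
   (default k = 9) and standardized per cell and calendar month through a
   fitted gamma distribution and the normal quantile function, giving the
   Standardized Precipitation Index SPI (mean 0, sd 1 over the calibration
   window). With several precipitation products, SPI is averaged across
   the ensemble. The annual drought index at each cell is the negative
   branch of harvest-month SPI:

   DI&#8209;t = −SPI(m, t) if SPI(m, t) < 0, else null,

   where m is the cell's harvest month.

2. **Yield anomaly.** Expected yield Ȳ is a per-cell local-polynomial
   (loess) trend; the anomaly is ΔY&#8209;t = (Y&#8209;t − Ȳ&#8209;t)/Ȳ&#8209;t × 100 (percent).

3. **Sensitivity.** Per cell, ordinary least squares of ΔY = a + β·DI over
   drought years, with a two-tailed t-test on β (significance P < 0.05).
   β is the percent yield change per unit drought magnitude; β < 0 means
   drought-induced loss. Summaries report shares of significant and
   negative cells (cell- or harvested-area-weighted), irrigated/rainfed
   splits (irrigated = more than 80% of harvested area irrigated), and
   area shares per sensitivity bin.

4. **Attribution.** A random forest (500 trees) regresses β on 22
   determinant rasters; skill is out-of-bag R²/RMSE, importance is
   impurity importance (share- and min–max-normalized), and partial
   dependence traces each determinant's marginal effect on β.

A synthetic-data module generates every input with known ground truth —
gamma precipitation with a zero-rain mass, yields with a planted β field,
predictors with known links — so each stage, and the pipeline end to end,
has a recovery test.

## Worked example

```r
library(droughtsens)
library(dplyr)

grid <- grid_spec(30, 40, -10, 0, resolution = 0.5)   # 20 x 20 cells
precip <- simulate_precipitation(grid, years = c(1981, 2016),
                                 n_datasets = 4, seed = 1)
spi <- ensemble_spi(compute_spi(precip, k = 9))
calendar <- simulate_crop_calendar(grid, "constant", month = 9)
di <- compute_di(spi, calendar)

set.seed(2)
sim <- simulate_predictors(grid)                      # planted beta field
yields <- simulate_yields(di, beta = sim$beta, sigma = 3, seed = 3)

anomalies <- yields |> fit_yield_trend() |> anomaly_percent()
records <- sensitivity_map(anomalies, di, n_min = 10)
summarize_sensitivity(records)
#> # A tibble: 1 × 6
#>   weighting n_cells share_significant share_negative_of_signific…¹ mean_beta_all
#>   <chr>       <int>             <dbl>                        <dbl>         <dbl>
#> 1 cells         400              86.8                         90.8         -7.77
```

The generator plants sensitivities around β₀ = −8 %/DI, and the recovered
map centres there: 86.8% of the 400 cells have a significant drought
response, 90.8% of those are negative (losses), and the mean β̂ is −7.77
percent yield change per unit drought index.

```r
features <- build_feature_table(records, sim$predictors, crop = "maize")
fit <- fit_attribution(features, n_trees = 500, seed = 4)
fit
#> <drought_attribution> 400 cells, 22 predictors, 500 trees
#>   OOB R^2 = 0.815, OOB RMSE = 2.728 %/DI
#>   top predictors: precipitation, organic_carbon, water_holding_capacity

head(tidy(fit), 4)
#> # A tibble: 4 × 5
#>   predictor              importance  share normalized  rank
#>   <chr>                       <dbl>  <dbl>      <dbl> <int>
#> 1 precipitation               4587. 0.289       1         1
#> 2 organic_carbon              2555. 0.161       0.547     2
#> 3 water_holding_capacity      1752. 0.111       0.368     3
#> 4 harvested_area              1407. 0.0888      0.291     4
```

The two determinants that actually drive the planted field
(`precipitation`, `water_holding_capacity`) carry the top raw importances
among the signal-bearing predictors; at only 400 cells a null field can
still slip between them (here `organic_carbon`), whereas at the test
suite's 2025-cell size the planted pair takes ranks 1–2 in every seeded
run. `partial_dependence(fit, "precipitation")` then traces the fitted
monotone link, and `autoplot(fit)`, `plot_sensitivity_map(records)`,
`plot_partial_dependence()` and `plot_area_share()` give the standard
figures.

The whole chain — including NetCDF artifacts, a per-cell CSV table, JSON
summaries, per-stage timings and MD5 hashes — can be driven from one
config: `run_pipeline(pipeline_config(...), out_dir)`.

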