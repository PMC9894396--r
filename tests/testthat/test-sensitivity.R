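test_that("per-cell OLS matches the closed-form oracle to 1e-10", {
  set.seed(20)
  for (rep in 1:5) {
    d <- sim_cell_pairs(20, beta = -6, a = 2, sigma = 4)
    fit <- fit_sensitivity(d, n_min = 10)
    or <- ols_oracle(d$di, d$anomaly)
    expect_equal(fit$intercept, or$a, tolerance = 1e-10)
    expect_equal(fit$beta, or$beta, tolerance = 1e-10)
    expect_equal(fit$se, or$se, tolerance = 1e-10)
    expect_equal(fit$p, or$p, tolerance = 1e-10)
  }
})

test_that("perfect linear response gives exact coefficients", {
  di <- c(0.2, 0.5, 1, 1.5, 2, 0.8, 1.2, 0.3, 1.8, 0.6, 1.1, 0.9)
  d <- tibble::tibble(di = di, anomaly = 2 - 3 * di)
  fit <- fit_sensitivity(d, n_min = 10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$beta, -3, tolerance = 1e-10)
  expect_lt(fit$p, 1e-10)
  expect_true(fit$significant)
})

test_that("degenerate records are flagged instead of fitted", {
  const <- tibble::tibble(di = rep(1.5, 12), anomaly = rnorm(12))
  fit <- fit_sensitivity(const, n_min = 10)
  expect_equal(fit$flag, "constant drought index")
  expect_true(is.na(fit$beta))

  few <- tibble::tibble(di = rexp(5), anomaly = rnorm(5))
  expect_equal(fit_sensitivity(few, n_min = 10)$flag,
               "insufficient drought years")
})

test_that("beta is shift-invariant in anomaly and scale-equivariant in DI", {
  set.seed(22)
  d <- sim_cell_pairs(24, beta = -5)
  f0 <- fit_sensitivity(d, n_min = 10)
  shifted <- dplyr::mutate(d, anomaly = anomaly + 7)
  f1 <- fit_sensitivity(shifted, n_min = 10)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-12)
  expect_equal(f1$intercept, f0$intercept + 7, tolerance = 1e-12)
  scaled <- dplyr::mutate(d, di = 2 * di)
  f2 <- fit_sensitivity(scaled, n_min = 10)
  expect_equal(f2$beta, f0$beta / 2, tolerance = 1e-12)
})

test_that("the DI-null policy switch changes which years enter", {
  set.seed(23)
  spi <- rnorm(36)
  d <- tibble::tibble(spi = spi,
                      di = ifelse(spi < 0, -spi, NA),
                      anomaly = -4 * ifelse(spi < 0, -spi, 0) + rnorm(36))
  drop <- fit_sensitivity(d, n_min = 5, di_policy = "drop")
  zero <- fit_sensitivity(d, n_min = 5, di_policy = "zero")
  expect_equal(drop$n, sum(spi < 0))
  expect_equal(zero$n, 36)
  # with spi present, zero policy distinguishes missing SPI from non-drought
  d2 <- d
  d2$spi[1:3] <- NA
  d2$di[1:3] <- NA
  expect_equal(fit_sensitivity(d2, n_min = 5, di_policy = "zero")$n, 33)
})

test_that("sensitivity_map recovers a planted heterogeneous field exactly", {
  gs <- tiny_grid(4)
  pr <- simulate_precipitation(gs, c(1981, 2016), n_datasets = 1,
                               noise_sd = 0, seed = 31)
  spi <- ensemble_spi(compute_spi(pr, k = 9))
  cal <- simulate_crop_calendar(gs, "constant", 9)
  di <- compute_di(spi, cal)
  truth <- grid_cells(gs)
  truth$beta <- -12 + 0.8 * seq_len(nrow(truth))
  y <- simulate_yields(di, truth, sigma = 0, base = 5, growth = 0.05)
  an <- anomaly_percent(y, trend_col = "trend_true")
  rec <- sensitivity_map(an, di, n_min = 5)
  cmp <- dplyr::inner_join(dplyr::filter(rec, is.na(flag)),
                           truth, by = c("lat", "lon"),
                           suffix = c("_hat", "_true"))
  expect_gt(nrow(cmp), 0.9 * nrow(truth))
  expect_lt(max(abs(cmp$beta_hat - cmp$beta_true)), 1e-8)

  # identical series in all cells give a uniform beta raster
  an_u <- an
  an_u <- dplyr::select(an_u, lat, lon, year, anomaly)
  one <- dplyr::filter(an, lat == an$lat[1], lon == an$lon[1])
  di_u <- di
  for (cc in seq_len(nrow(truth))) {
    idx <- an_u$lat == truth$lat[cc] & an_u$lon == truth$lon[cc]
    an_u$anomaly[idx] <- one$anomaly
    jdx <- di_u$lat == truth$lat[cc] & di_u$lon == truth$lon[cc]
    di_u$di[jdx] <- dplyr::filter(di, lat == an$lat[1], lon == an$lon[1])$di
  }
  rec_u <- sensitivity_map(an_u, di_u, n_min = 5)
  betas <- rec_u$beta[is.na(rec_u$flag)]
  expect_lt(diff(range(betas)), 1e-10)
})

test_that("summaries match a brute-force tally, weighted and unweighted", {
  set.seed(24)
  n <- 60
  rec <- tibble::tibble(
    lat = rep(seq(0.25, length.out = n, by = 0.5), 1), lon = 0.25,
    n = 20, intercept = 0,
    beta = rnorm(n, -4, 6), se = 1,
    p = runif(n), significant = NA, flag = NA_character_)
  rec$significant <- rec$p < 0.05
  area <- tibble::tibble(lat = rec$lat, lon = rec$lon,
                         harvested_area = runif(n, 10, 1000))

  s_cells <- summarize_sensitivity(rec, weighting = "cells")
  expect_equal(s_cells$share_significant, 100 * mean(rec$significant))
  expect_equal(s_cells$mean_beta_all, mean(rec$beta))
  sig <- rec$significant
  if (any(sig)) {
    expect_equal(s_cells$share_negative_of_significant,
                 100 * mean(rec$beta[sig] < 0))
    expect_equal(s_cells$mean_beta_significant, mean(rec$beta[sig]))
  }

  s_area <- summarize_sensitivity(rec, area, weighting = "area")
  w <- area$harvested_area
  expect_equal(s_area$share_significant, 100 * sum(w[sig]) / sum(w))
  expect_equal(s_area$mean_beta_all, weighted.mean(rec$beta, w))
  expect_error(summarize_sensitivity(rec, weighting = "area"),
               "harvested_area")

  # two equal-area cells at -10 and 0 average to -5
  two <- rec[1:2, ]
  two$beta <- c(-10, 0)
  expect_equal(summarize_sensitivity(two, weighting = "cells")$mean_beta_all, -5)
  all_sig_neg <- dplyr::mutate(rec, significant = TRUE, beta = -abs(beta))
  expect_equal(summarize_sensitivity(all_sig_neg,
                                     weighting = "cells")$share_negative_of_significant,
               100)
})

test_that("irrigation classification applies a strict 0.8 threshold", {
  fr <- tibble::tibble(lat = c(1, 1, 1, 1), lon = 1:4,
                       frac = c(0.81, 0.80, 0.2, NA))
  cls <- classify_irrigation(fr)
  expect_equal(as.character(cls$class),
               c("irrigated", "rainfed", "rainfed", "unclassified"))

  set.seed(25)
  rnd <- tibble::tibble(lat = 1, lon = seq_len(200), frac = runif(200))
  cls2 <- classify_irrigation(rnd, threshold = 0.8)
  expect_equal(as.character(cls2$class),
               ifelse(rnd$frac > 0.8, "irrigated", "rainfed"))
  expect_error(classify_irrigation(dplyr::mutate(fr, frac = c(2, 0, 0, 0))),
               "invalid fraction")
})

test_that("area shares histogram beta as the loop oracle does", {
  # two equal-area cells at -7 and +7 with width 5: bins [-10,-5) and [5,10)
  rec <- tibble::tibble(lat = c(1.25, 1.75), lon = 0.25, n = 20,
                        intercept = 0, beta = c(-7, 7), se = 1, p = 0.5,
                        significant = FALSE, flag = NA_character_)
  cls <- tibble::tibble(lat = rec$lat, lon = rec$lon,
                        irrigated_fraction = 0.1,
                        class = factor("rainfed",
                                       levels = c("irrigated", "rainfed",
                                                  "unclassified")))
  area <- tibble::tibble(lat = rec$lat, lon = rec$lon, a = c(50, 50))
  bins <- binned_area_share(rec, cls, area, bin_width = 5)
  expect_equal(bins$bin_lo, c(-10, 5))
  expect_equal(bins$share, c(50, 50))

  # all beta in one bin -> 100%
  rec1 <- dplyr::mutate(rec, beta = c(-7, -6))
  bins1 <- binned_area_share(rec1, cls, area, bin_width = 5)
  expect_equal(bins1$share, 100)

  # seeded map equals a brute-force weighted histogram, per class
  set.seed(26)
  n <- 150
  rec2 <- tibble::tibble(lat = seq(0.25, by = 0.5, length.out = n), lon = 0.25,
                         n = 20, intercept = 0, beta = rnorm(n, -3, 8),
                         se = 1, p = 0.5, significant = FALSE,
                         flag = NA_character_)
  cls2 <- tibble::tibble(lat = rec2$lat, lon = rec2$lon,
                         irrigated_fraction = runif(n),
                         class = factor(sample(c("irrigated", "rainfed"), n,
                                               replace = TRUE),
                                        levels = c("irrigated", "rainfed",
                                                   "unclassified")))
  area2 <- tibble::tibble(lat = rec2$lat, lon = rec2$lon, a = runif(n, 1, 100))
  bins2 <- binned_area_share(rec2, cls2, area2, bin_width = 5)
  for (k in seq_len(nrow(bins2))) {
    in_bin <- cls2$class == bins2$class[k] &
      rec2$beta >= bins2$bin_lo[k] & rec2$beta < bins2$bin_hi[k]
    cls_total <- sum(area2$a[cls2$class == bins2$class[k]])
    expect_equal(bins2$share[k], 100 * sum(area2$a[in_bin]) / cls_total)
  }
  # shares sum to 100 within each class
  sums <- tapply(bins2$share, droplevels(bins2$class), sum)
  expect_true(all(abs(sums - 100) < 0.01))
})
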