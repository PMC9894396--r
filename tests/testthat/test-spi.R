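test_that("accumulation matches the brute-force rolling sum", {
  # k = 1 is the identity
  x <- c(5, 0, 12, 3, 7, 1, 9, 2, 8, 4, 6, 10)
  p <- cell_precip(x)
  a1 <- accumulate_precip(p, k = 1)
  expect_equal(a1$accum, x)

  # constant 10 mm/month, k = 9 => 90 mm after month 9
  p10 <- cell_precip(rep(10, 24))
  a9 <- accumulate_precip(p10, k = 9)
  expect_true(all(is.na(a9$accum[1:8])))
  expect_true(all(a9$accum[9:24] == 90))

  # random 24-month series, k = 3: equals the naive loop oracle
  set.seed(3)
  x <- rgamma(24, 3, scale = 20)
  x[7] <- NA # a missing contributor poisons its windows
  a3 <- accumulate_precip(cell_precip(x), k = 3)
  expect_equal(a3$accum, naive_rolling_sum(x, 3))
  expect_error(accumulate_precip(cell_precip(rep(1, 12)), k = 13),
               "timescale too long")
})

test_that("Thom's gamma estimator is consistent and flags degeneracies", {
  set.seed(8)
  x <- rgamma(1e4, shape = 2, scale = 50)
  fit <- fit_gamma_thom(x)
  expect_false(fit$degenerate)
  expect_gt(fit$shape, 1.9)
  expect_lt(fit$shape, 2.1)
  expect_equal(fit$shape * fit$scale, mean(x), tolerance = 1e-10)

  # identical nonzero values (zero log-dispersion): degenerate, no crash
  expect_true(fit_gamma_thom(rep(7, 36))$degenerate)
  # fewer than 3 nonzero values: degenerate
  expect_true(fit_gamma_thom(c(0, 0, 1, 2))$degenerate)
  expect_true(fit_gamma_thom(rep(0, 36))$degenerate)
  # zero fraction is counted over the finite sample
  s <- c(rep(0, 6), rgamma(30, 2, scale = 10))
  expect_equal(fit_gamma_thom(s)$q_zero, 1 / 6)
})

test_that("Thom's estimator agrees with independent maximum likelihood", {
  skip_if_not_installed("MASS")
  set.seed(9)
  x <- rgamma(5000, shape = 2, scale = 50)
  thom <- fit_gamma_thom(x)
  # optimizer probes invalid parameter regions en route (NaN warnings)
  mle <- suppressWarnings(
    MASS::fitdistr(x, "gamma", start = list(shape = 1, rate = 1 / 50)))$estimate
  expect_equal(thom$shape, unname(mle["shape"]), tolerance = 0.05)
  expect_equal(thom$scale, 1 / unname(mle["rate"]), tolerance = 0.05)
})

test_that("SPI standardization maps fitted quantiles to normal deviates", {
  set.seed(21)
  x <- rgamma(36 * 50, shape = 3, scale = 30)
  p <- cell_precip(x[seq_len(432)])
  a <- accumulate_precip(p, k = 1)
  fits <- fit_precip_gamma(a)
  spi <- spi_transform(a, fits)

  # accumulation at the fitted median -> SPI = 0
  f1 <- fits[fits$month == 1, ]
  med <- qgamma(0.5, shape = f1$shape, scale = f1$scale)
  a_med <- a
  a_med$accum[a_med$month == 1] <- med
  s_med <- spi_transform(a_med, fits)
  expect_equal(s_med$spi[s_med$month == 1], rep(0, 36), tolerance = 1e-10)

  # accumulation at the 97.725th percentile of H -> SPI = 2.00
  q977 <- qgamma(pnorm(2), shape = f1$shape, scale = f1$scale)
  a_q <- a
  a_q$accum[a_q$month == 1] <- q977
  s_q <- spi_transform(a_q, fits)
  expect_equal(s_q$spi[s_q$month == 1], rep(2, 36), tolerance = 0.01)

  # degenerate fit propagates missing SPI
  a0 <- a
  a0$accum[a0$month == 2] <- 0
  s0 <- spi_transform(a0)
  expect_true(all(is.na(s0$spi[s0$month == 2])))
})

test_that("SPI rank order equals the empirical quantile transform", {
  set.seed(33)
  one_cell <- grid_spec(0, 0.5, 0, 0.5, 0.5)
  pr <- simulate_precipitation(one_cell, c(1, 834), n_datasets = 1,
                               shape = 2.5, scale = 30, zero_prob = 0.1,
                               noise_sd = 0, seed = 33)
  spi <- compute_spi(pr, k = 1)
  m1 <- spi[spi$month == 1, ]
  ranks_spi <- rank(m1$spi)
  ranks_emp <- rank(rank(pr$precip[pr$month == 1])) # empirical CDF oracle
  expect_gt(cor(ranks_spi, ranks_emp, method = "spearman"), 0.999)
})

test_that("zero months get the mixed-distribution plugin H(0) = q/2", {
  set.seed(55)
  x <- rgamma(144, shape = 3, scale = 25) # 12 years
  jan_idx <- seq(1, 144, 12)
  x[jan_idx[1:4]] <- 0 # 4 of 12 Januaries exactly dry
  a <- accumulate_precip(cell_precip(x), k = 1)
  fits <- fit_precip_gamma(a)
  f1 <- fits[fits$month == 1, ]
  expect_equal(f1$q_zero, 4 / 12)
  spi <- spi_transform(a, fits)
  jan <- spi$spi[spi$month == 1][x[jan_idx] == 0]
  expect_equal(jan, rep(qnorm(f1$q_zero / 2), 4), tolerance = 1e-10)
})

test_that("SPI is clipped, calibrated and monotone in accumulation", {
  gs <- tiny_grid(3)
  pr <- simulate_precipitation(gs, c(1981, 2016), n_datasets = 1,
                               noise_sd = 0, seed = 13)
  spi <- compute_spi(pr, k = 9)
  expect_true(all(abs(spi$spi) <= 3.09, na.rm = TRUE))
  expect_true(all(is.na(spi$spi[spi$year == 1981 & spi$month <= 8])))

  # calibration: per cell-month mean ~0, sd ~1 over the window
  calib <- spi |>
    dplyr::filter(!is.na(spi)) |>
    dplyr::group_by(lat, lon, month) |>
    dplyr::summarise(m = mean(spi), s = sd(spi), .groups = "drop")
  expect_lt(max(abs(calib$m)), 0.05)
  expect_lt(max(abs(calib$s - 1)), 0.15)

  # monotonicity: raising one month's accumulation never lowers its SPI
  a <- accumulate_precip(pr, k = 9)
  fits <- fit_precip_gamma(a)
  s1 <- spi_transform(a, fits)
  a2 <- a
  bump <- a2$year == 2000 & a2$month == 9
  a2$accum[bump] <- a2$accum[bump] + 50
  s2 <- spi_transform(a2, fits)
  expect_true(all(s2$spi[bump] >= s1$spi[bump], na.rm = TRUE))
})

test_that("ensemble averaging matches the loop oracle and its identities", {
  gs <- tiny_grid(2)
  pr <- simulate_precipitation(gs, c(1981, 2016), n_datasets = 8,
                               noise_sd = 6, seed = 17)
  spi <- compute_spi(pr, k = 9)
  ens <- ensemble_spi(spi)

  # brute-force mean across members
  oracle <- aggregate(spi ~ lat + lon + year + month, data = spi,
                      FUN = mean, na.action = stats::na.pass, na.rm = TRUE)
  m <- dplyr::inner_join(ens, oracle, by = c("lat", "lon", "year", "month"),
                         suffix = c("", ".or"))
  expect_equal(m$spi, ifelse(is.nan(m$spi.or), NA, m$spi.or), tolerance = 1e-12)

  # single member: identity
  one <- spi[spi$dataset == "synth01", ]
  expect_equal(ensemble_spi(one)$spi,
               dplyr::arrange(one, lat, lon, year, month)$spi)
  # members {-1, 0, +1} average to 0
  toy <- tibble::tibble(dataset = c("a", "b", "c"), lat = 1, lon = 1,
                        year = 2000, month = 1, spi = c(-1, 0, 1))
  expect_equal(ensemble_spi(toy)$spi, 0)
  # mismatched axes are rejected
  expect_error(ensemble_spi(spi[-1, ]), "ensemble axis mismatch")
})

test_that("the drought index is the negative branch of harvest-month SPI", {
  gs <- tiny_grid(2)
  pr <- simulate_precipitation(gs, c(1981, 2016), n_datasets = 1,
                               noise_sd = 0, seed = 19)
  spi <- ensemble_spi(compute_spi(pr, k = 9))
  cal <- simulate_crop_calendar(gs, "constant", month = 9)
  di <- compute_di(spi, cal)

  # brute-force loop over the seeded grid
  for (i in seq_len(nrow(di))) {
    s <- spi$spi[spi$lat == di$lat[i] & spi$lon == di$lon[i] &
                   spi$year == di$year[i] & spi$month == 9]
    if (is.na(s) || s >= 0) {
      expect_true(is.na(di$di[i]))
    } else {
      expect_identical(di$di[i], -s)
    }
  }
  # boundary: SPI = 0 belongs to the null branch; SPI = -1.2 -> DI = 1.2
  toy <- tibble::tibble(lat = 0.25, lon = 0.25, year = 2000:2002,
                        month = 9, spi = c(-1.2, 0.5, 0))
  toy_cal <- tibble::tibble(lat = 0.25, lon = 0.25, harvest_month = 9)
  toy_di <- compute_di(toy, toy_cal)
  expect_equal(toy_di$di, c(1.2, NA, NA))
  # accounting identity: defined DI years + (SPI >= 0) years = finite SPI years
  n_def <- sum(!is.na(di$di))
  n_pos <- sum(di$spi >= 0, na.rm = TRUE)
  expect_equal(n_def + n_pos, sum(!is.na(di$spi)))

  bad_cal <- dplyr::mutate(cal, harvest_month = 13)
  expect_error(compute_di(spi, bad_cal), "invalid calendar")
})
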