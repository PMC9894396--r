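#' Accumulate monthly precipitation over a k-month window
#'
#' Rolling k-month precipitation totals per cell (and per ensemble member if
#' a `dataset` column is present). The value at month t is the sum of months
#' t-k+1..t; the first k-1 months of each record are missing, and any
#' missing contributor makes the whole window missing.
#'
#' @param precip Monthly precipitation tibble (`lat`, `lon`, `year`,
#'   `month`, `precip`, optional `dataset`).
#' @param k Accumulation timescale in months (default 9, the scale most
#'   indicative of long-term precipitation deficit for annual crops).
#' @return The same tibble with an `accum` column replacing `precip`.
#' @export
accumulate_precip <- function(precip, k = 9) {
  stopifnot(all(c("lat", "lon", "year", "month", "precip") %in% names(precip)))
  if (k < 1) stop("timescale must be >= 1", call. = FALSE)
  group_cols <- intersect(c("dataset", "lat", "lon"), names(precip))
  out <- precip |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_cols, "year", "month")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols)))
  n_per <- dplyr::group_size(out)
  if (any(n_per < k)) {
    stop("timescale too long: k = ", k, " exceeds a record of length ",
         min(n_per), call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(accum = zoo::rollapplyr(.data$precip, k, sum, fill = NA)) |>
    dplyr::ungroup()
  out$precip <- NULL
  out
}

#' Fit a mixed gamma distribution by Thom's approximation
#'
#' Fits the gamma shape and scale to the strictly positive values of a
#' sample by Thom's closed-form approximation
#' (`A = log(mean) - mean(log x)`; `shape = (1 + sqrt(1 + 4A/3)) / (4A)`;
#' `scale = mean / shape`) and records the fraction of exact zeros, giving
#' the mixed dry/wet distribution used for SPI standardization. Samples with
#' fewer than 3 positive values, or with zero log-dispersion (all positive
#' values identical), are flagged degenerate rather than fitted.
#'
#' @param x Numeric sample (one cell, one calendar month, across years);
#'   `NA`s are ignored.
#' @return One-row tibble: `shape`, `scale`, `q_zero`, `n_fit`, `degenerate`.
#' @export
fit_gamma_thom <- function(x) {
  x <- x[is.finite(x)]
  n_fit <- length(x)
  nz <- x[x > 0]
  q_zero <- if (n_fit > 0) sum(x == 0) / n_fit else NA_real_
  if (length(nz) < 3) {
    return(tibble::tibble(shape = NA_real_, scale = NA_real_,
                          q_zero = q_zero, n_fit = n_fit, degenerate = TRUE))
  }
  xbar <- mean(nz)
  a <- log(xbar) - mean(log(nz))
  if (!is.finite(a) || a <= 0) {
    return(tibble::tibble(shape = NA_real_, scale = NA_real_,
                          q_zero = q_zero, n_fit = n_fit, degenerate = TRUE))
  }
  shape <- (1 + sqrt(1 + 4 * a / 3)) / (4 * a)
  tibble::tibble(shape = shape, scale = xbar / shape,
                 q_zero = q_zero, n_fit = n_fit, degenerate = FALSE)
}

#' Fit per-cell, per-calendar-month gamma distributions to accumulations
#'
#' @param accum Accumulated precipitation tibble from [accumulate_precip()].
#' @param calibration Optional `c(start_year, end_year)` window restricting
#'   the years used for fitting (default: all years present, i.e. the full
#'   analysis window).
#' @return A tibble keyed by (`dataset`,) `lat`, `lon`, `month` with the
#'   [fit_gamma_thom()] columns.
#' @export
fit_precip_gamma <- function(accum, calibration = NULL) {
  stopifnot(all(c("lat", "lon", "year", "month", "accum") %in% names(accum)))
  fit_data <- accum
  if (!is.null(calibration)) {
    fit_data <- dplyr::filter(fit_data, .data$year >= calibration[1],
                              .data$year <= calibration[2])
  }
  group_cols <- intersect(c("dataset", "lat", "lon", "month"), names(accum))
  fit_data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::reframe(fit_gamma_thom(.data$accum))
}

#' Standardize accumulated precipitation into SPI
#'
#' Maps each accumulation through the fitted mixed-gamma CDF
#' `H(x) = q_zero + (1 - q_zero) * G(x)` for `x > 0` and `H(0) = q_zero / 2`,
#' then through the standard-normal quantile function, producing a deviate
#' with mean ~0 and sd ~1 over the calibration window. Values are clipped to
#' `±clip` so empirical tail excursions never yield infinite deviates. Cells
#' or calendar months with a degenerate gamma fit give missing SPI.
#'
#' @inheritParams fit_precip_gamma
#' @param fits Gamma fit table from [fit_precip_gamma()]; computed from
#'   `accum` (with `calibration`) when omitted.
#' @param clip Symmetric clip bound for SPI (default 3.09, the standard
#'   normal 0.001/0.999 quantile).
#' @return The accumulation tibble with an `spi` column replacing `accum`.
#' @export
spi_transform <- function(accum, fits = NULL, clip = 3.09, calibration = NULL) {
  if (is.null(fits)) fits <- fit_precip_gamma(accum, calibration = calibration)
  group_cols <- intersect(c("dataset", "lat", "lon", "month"), names(accum))
  out <- dplyr::left_join(accum, fits, by = group_cols)
  h <- ifelse(out$accum > 0,
              out$q_zero + (1 - out$q_zero) *
                stats::pgamma(out$accum, shape = out$shape, scale = out$scale),
              out$q_zero / 2)
  h[out$degenerate | is.na(out$accum)] <- NA
  out$spi <- pmin(pmax(stats::qnorm(h), -clip), clip)
  out[, c(setdiff(names(accum), "accum"), "spi")]
}

#' Compute SPI from monthly precipitation
#'
#' Convenience wrapper: [accumulate_precip()] then [fit_precip_gamma()] then
#' [spi_transform()], per ensemble member if a `dataset` column is present.
#'
#' @inheritParams accumulate_precip
#' @inheritParams spi_transform
#' @return SPI tibble (`dataset`,) `lat`, `lon`, `year`, `month`, `spi`.
#' @examples
#' gs <- grid_spec(0, 1, 0, 1, 0.5)
#' pr <- simulate_precipitation(gs, c(1981, 2016), n_datasets = 1, seed = 1)
#' spi <- compute_spi(pr, k = 9)
#' @export
compute_spi <- function(precip, k = 9, calibration = NULL, clip = 3.09) {
  accum <- accumulate_precip(precip, k = k)
  spi_transform(accum, calibration = calibration, clip = clip)
}

#' Average SPI across ensemble members
#'
#' Element-wise mean over members at each (cell, year, month); a cell-month
#' missing in some members is averaged over the finite ones, and stays
#' missing only when missing in all. Because products correlate, averaging
#' is done on the standardized index, not on raw precipitation.
#'
#' @param spi SPI tibble with a `dataset` column (one SPI per member).
#' @return SPI tibble without `dataset`, same axes.
#' @export
ensemble_spi <- function(spi) {
  if (!"dataset" %in% names(spi)) return(spi)
  key_cols <- intersect(c("lat", "lon", "year", "month"), names(spi))
  n_members <- dplyr::n_distinct(spi$dataset)
  keys <- dplyr::distinct(spi[, key_cols])
  if (nrow(spi) != n_members * nrow(keys)) {
    stop("ensemble axis mismatch: members do not share identical grid/time axes",
         call. = FALSE)
  }
  spi |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      spi = if (all(is.na(.data$spi))) NA_real_ else mean(.data$spi, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Project SPI onto the harvest month as an annual drought index
#'
#' For each cell and year, the drought index is the magnitude of negative
#' SPI at that cell's harvest month: `DI = -SPI` when `SPI < 0`, and missing
#' (null) when `SPI >= 0` or SPI itself is missing. The harvest month is a
#' static raster applied identically to every year.
#'
#' @param spi Ensemble (or single-member) SPI tibble `lat`, `lon`, `year`,
#'   `month`, `spi`.
#' @param calendar Harvest-month raster `lat`, `lon`, `harvest_month`
#'   (integers 1-12), as from [simulate_crop_calendar()].
#' @return A tibble `lat`, `lon`, `year`, `harvest_month`, `spi`, `di`
#'   where `spi` is the harvest-month SPI and `di >= 0` or `NA`.
#' @export
compute_di <- function(spi, calendar) {
  stopifnot(all(c("lat", "lon", "year", "month", "spi") %in% names(spi)))
  value_col <- setdiff(names(calendar), c("lat", "lon"))
  if (length(value_col) != 1) {
    stop("calendar must have exactly one harvest-month column", call. = FALSE)
  }
  hm <- calendar[[value_col]]
  if (any(!is.na(hm) & (hm < 1 | hm > 12 | hm != round(hm)))) {
    stop("invalid calendar: harvest months must be integers in 1..12",
         call. = FALSE)
  }
  cal <- calendar
  names(cal)[names(cal) == value_col] <- "harvest_month"
  spi |>
    dplyr::inner_join(cal, by = c("lat", "lon")) |>
    dplyr::filter(.data$month == .data$harvest_month) |>
    dplyr::mutate(di = ifelse(!is.na(.data$spi) & .data$spi < 0,
                              -.data$spi, NA_real_)) |>
    dplyr::select(dplyr::all_of(c("lat", "lon", "year", "harvest_month",
                                  "spi", "di"))) |>
    dplyr::arrange(.data$lat, .data$lon, .data$year)
}
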