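#' Fit the drought sensitivity of one yield series
#'
#' Ordinary least squares of percent yield anomaly on the drought index,
#' `anomaly = a + beta * DI`, with the slope's two-tailed t-test p-value
#' (n - 2 degrees of freedom). Under the default `di_policy = "drop"`,
#' non-drought years (missing DI) are excluded, so the regression runs over
#' drought years only; `di_policy = "zero"` instead enters non-drought years
#' with DI = 0 (distinguished from years whose SPI itself is missing via
#' the `spi` column when present).
#'
#' @param data Tibble with `anomaly` and `di` columns (and optionally `spi`)
#'   for a single cell.
#' @param n_min Minimum usable years (default 10); below it the record is
#'   flagged and estimates are missing.
#' @param di_policy `"drop"` (non-drought years excluded) or `"zero"`.
#' @return One-row tibble: `n`, `intercept`, `beta`, `se`, `p`,
#'   `significant` (`p < 0.05`), `flag` (`NA` when the fit is valid).
#' @examples
#' d <- tibble::tibble(di = c(0.2, 0.5, 1, 1.5, 2, 0.8, 1.2, 0.3, 1.8, 0.6,
#'                            1.1, 0.9),
#'                     anomaly = 2 - 3 * di)
#' fit_sensitivity(d) # recovers a = 2, beta = -3
#' @export
fit_sensitivity <- function(data, n_min = 10,
                            di_policy = c("drop", "zero")) {
  di_policy <- match.arg(di_policy)
  stopifnot(all(c("anomaly", "di") %in% names(data)))
  x <- data$di
  if (di_policy == "zero") {
    if ("spi" %in% names(data)) {
      x <- ifelse(is.na(data$spi), NA_real_,
                  ifelse(data$spi < 0, -data$spi, 0))
    } else {
      x <- ifelse(is.na(x), 0, x)
    }
  }
  y <- data$anomaly
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)

  empty <- function(flag) {
    tibble::tibble(n = n, intercept = NA_real_, beta = NA_real_,
                   se = NA_real_, p = NA_real_, significant = FALSE,
                   flag = flag)
  }
  if (n < max(n_min, 3)) return(empty("insufficient drought years"))
  if (stats::var(x) == 0) return(empty("constant drought index"))

  fit <- stats::lm(y ~ x)
  # a numerically perfect fit (zero residual variance) is legitimate here
  # (noise-free synthetic recovery); silence summary.lm's reliability note
  cf <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(n = n,
                 intercept = cf[1, 1],
                 beta = cf[2, 1],
                 se = cf[2, 2],
                 p = cf[2, 4],
                 significant = cf[2, 4] < 0.05,
                 flag = NA_character_)
}

#' Map drought sensitivity across a grid
#'
#' Joins anomalies and drought index by cell-year and fits
#' [fit_sensitivity()] in every cell.
#'
#' @param anomalies Tibble `lat`, `lon`, `year`, `anomaly` (from
#'   [anomaly_percent()]).
#' @param di Drought-index tibble `lat`, `lon`, `year`, `di` (and `spi`)
#'   from [compute_di()].
#' @inheritParams fit_sensitivity
#' @return A tibble with one row per cell: `lat`, `lon` plus the
#'   [fit_sensitivity()] record columns. Cells flagged (insufficient years,
#'   constant DI) carry missing estimates rather than being dropped.
#' @export
sensitivity_map <- function(anomalies, di, n_min = 10,
                            di_policy = c("drop", "zero")) {
  di_policy <- match.arg(di_policy)
  stopifnot(all(c("lat", "lon", "year", "anomaly") %in% names(anomalies)),
            all(c("lat", "lon", "year", "di") %in% names(di)))
  di_cols <- intersect(c("lat", "lon", "year", "spi", "di"), names(di))
  joined <- dplyr::inner_join(anomalies, di[, di_cols],
                              by = c("lat", "lon", "year"))
  joined |>
    dplyr::group_by(.data$lat, .data$lon) |>
    dplyr::group_modify(~ fit_sensitivity(.x, n_min = n_min,
                                          di_policy = di_policy)) |>
    dplyr::ungroup()
}

#' Summarize sensitivity records across cropland
#'
#' Global (or regional) summaries of a sensitivity map: the share of
#' evaluated cells with a significant drought response, the share of those
#' that are negative (drought losses), and the mean sensitivity over all and
#' over significant cells — each either unweighted (`"cells"`) or weighted
#' by harvested area.
#'
#' @param records Sensitivity records from [sensitivity_map()].
#' @param harvested_area Static raster tibble (`lat`, `lon`, one value
#'   column, e.g. km2) required for `weighting = "area"`.
#' @param weighting `"cells"` or `"area"`.
#' @return One-row tibble: `weighting`, `n_cells`, `share_significant`,
#'   `share_negative_of_significant`, `mean_beta_all`,
#'   `mean_beta_significant` (shares in percent).
#' @export
summarize_sensitivity <- function(records, harvested_area = NULL,
                                  weighting = c("cells", "area")) {
  weighting <- match.arg(weighting)
  valid <- dplyr::filter(records, is.na(.data$flag))
  if (nrow(valid) == 0) stop("no evaluable sensitivity records", call. = FALSE)

  if (weighting == "area") {
    if (is.null(harvested_area)) {
      stop("harvested_area raster is required for area weighting",
           call. = FALSE)
    }
    area_col <- setdiff(names(harvested_area), c("lat", "lon"))
    stopifnot(length(area_col) == 1)
    valid <- dplyr::inner_join(
      valid,
      stats::setNames(harvested_area, c("lat", "lon", ".w")),
      by = c("lat", "lon"))
    valid <- dplyr::filter(valid, is.finite(.data$.w), .data$.w > 0)
  } else {
    valid$.w <- 1
  }

  wshare <- function(flag, w) 100 * sum(w[flag]) / sum(w)
  sig <- valid$significant
  tibble::tibble(
    weighting = weighting,
    n_cells = nrow(valid),
    share_significant = wshare(sig, valid$.w),
    share_negative_of_significant =
      if (any(sig)) wshare(valid$beta[sig] < 0, valid$.w[sig]) else NA_real_,
    mean_beta_all = stats::weighted.mean(valid$beta, valid$.w),
    mean_beta_significant =
      if (any(sig)) stats::weighted.mean(valid$beta[sig], valid$.w[sig])
      else NA_real_
  )
}

#' Classify cells as irrigated or rainfed
#'
#' A cell is irrigated when strictly more than `threshold` (default 80%) of
#' its harvested area is irrigated, rainfed otherwise; cells with unknown
#' fraction are unclassified.
#'
#' @param fraction Static raster tibble `lat`, `lon` plus one column of
#'   irrigated fractions in \eqn{[0, 1]}.
#' @param threshold Classification threshold (default 0.8; the boundary
#'   value itself is rainfed).
#' @return Tibble `lat`, `lon`, `irrigated_fraction`, `class` (factor
#'   irrigated/rainfed/unclassified).
#' @export
classify_irrigation <- function(fraction, threshold = 0.8) {
  value_col <- setdiff(names(fraction), c("lat", "lon"))
  stopifnot(length(value_col) == 1)
  f <- fraction[[value_col]]
  if (any(is.finite(f) & (f < 0 | f > 1))) {
    stop("invalid fraction: irrigated fractions must lie in [0, 1]",
         call. = FALSE)
  }
  cls <- ifelse(is.na(f), "unclassified",
                ifelse(f > threshold, "irrigated", "rainfed"))
  tibble::tibble(lat = fraction$lat, lon = fraction$lon,
                 irrigated_fraction = f,
                 class = factor(cls, levels = c("irrigated", "rainfed",
                                                "unclassified")))
}

#' Harvested-area share per sensitivity bin and irrigation class
#'
#' Histograms the sensitivity map by half-open bins `[lo, hi)` of width
#' `bin_width`, symmetric about zero, weighting each cell by its harvested
#' area and normalizing to 100% within each irrigation class.
#'
#' @param records Sensitivity records (uses `beta`; flagged cells excluded).
#' @param classes Irrigation class map from [classify_irrigation()].
#' @param harvested_area Static raster tibble `lat`, `lon` + area column.
#' @param bin_width Bin width in percent per unit drought index (default 5).
#' @return Tibble `class`, `bin_lo`, `bin_hi`, `bin_mid`, `area`, `share`
#'   (percent; shares sum to 100 within each class). Classes with zero
#'   total area are absent.
#' @export
binned_area_share <- function(records, classes, harvested_area,
                              bin_width = 5) {
  stopifnot(bin_width > 0)
  area_col <- setdiff(names(harvested_area), c("lat", "lon"))
  stopifnot(length(area_col) == 1)
  df <- records |>
    dplyr::filter(is.na(.data$flag), is.finite(.data$beta)) |>
    dplyr::inner_join(classes[, c("lat", "lon", "class")],
                      by = c("lat", "lon")) |>
    dplyr::inner_join(stats::setNames(harvested_area, c("lat", "lon", ".w")),
                      by = c("lat", "lon")) |>
    dplyr::filter(is.finite(.data$.w), .data$.w > 0,
                  .data$class != "unclassified")
  if (nrow(df) == 0) {
    return(tibble::tibble(class = factor(character(),
                                         levels = levels(classes$class)),
                          bin_lo = numeric(), bin_hi = numeric(),
                          bin_mid = numeric(), area = numeric(),
                          share = numeric()))
  }
  # half-open [lo, hi) bins anchored so 0 is an edge
  df$bin_lo <- bin_width * floor(df$beta / bin_width)
  df |>
    dplyr::group_by(.data$class, .data$bin_lo) |>
    dplyr::summarise(area = sum(.data$.w), .groups = "drop_last") |>
    dplyr::mutate(share = 100 * .data$area / sum(.data$area)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_hi = .data$bin_lo + bin_width,
                  bin_mid = .data$bin_lo + bin_width / 2) |>
    dplyr::select(dplyr::all_of(c("class", "bin_lo", "bin_hi", "bin_mid",
                                  "area", "share"))) |>
    dplyr::arrange(.data$class, .data$bin_lo)
}
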