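#' Fit a smooth expected-yield trend by local polynomial regression
#'
#' Per grid cell, the long-term expected yield is estimated by
#' locally-weighted polynomial regression (tricube weights) of yield on
#' year, evaluated at the observed years only. The trend absorbs the slow
#' technology- and management-driven evolution of yields; what remains is
#' read as climate-driven. Cells with fewer than `max(4, degree + 2)`
#' finite years are left untrendable (missing trend).
#'
#' @param yields Tibble `lat`, `lon`, `year`, `yield` (t/ha; `NA` allowed).
#' @param span Smoothing span: fraction of the record in each local
#'   neighbourhood (default 0.67).
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @return The input with a `trend` column (t/ha, `NA` where untrendable or
#'   yield missing).
#' @examples
#' yr <- tibble::tibble(lat = 0.25, lon = 0.25, year = 1981:2016,
#'                      yield = 3 + 0.04 * (1981:2016 - 1981))
#' ft <- fit_yield_trend(yr, degree = 1)
#' all.equal(ft$trend, ft$yield) # local fit reproduces an affine series
#' @export
fit_yield_trend <- function(yields, span = 0.67, degree = 2) {
  stopifnot(all(c("lat", "lon", "year", "yield") %in% names(yields)))
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]", call. = FALSE)
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)

  fit_one <- function(df, ...) {
    ok <- is.finite(df$yield)
    df$trend <- NA_real_
    if (sum(ok) >= max(4, degree + 2)) {
      fit <- tryCatch(
        stats::loess(yield ~ year, data = df[ok, ], span = span,
                     degree = degree, family = "gaussian",
                     surface = "direct"),
        error = function(e) NULL)
      if (!is.null(fit)) {
        df$trend[ok] <- stats::predict(fit, newdata = df[ok, ])
      }
    }
    df
  }
  yields |>
    dplyr::group_by(.data$lat, .data$lon) |>
    dplyr::group_modify(fit_one) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("lat", "lon",
                                  setdiff(names(yields), c("lat", "lon")),
                                  "trend")))
}

#' Convert yields to percent anomalies around the trend
#'
#' `anomaly = (yield - trend) / trend * 100`. Cell-years with a non-positive
#' trend are disqualified (set missing) rather than allowed to produce
#' explosive percentages; one warning reports how many.
#'
#' @param yields Tibble with `yield` and a trend column.
#' @param trend_col Name of the trend column (default `"trend"`; pass
#'   `"trend_true"` to compute anomalies against a known generator trend).
#' @return The input with an `anomaly` column (percent).
#' @export
anomaly_percent <- function(yields, trend_col = "trend") {
  stopifnot("yield" %in% names(yields), trend_col %in% names(yields))
  trend <- yields[[trend_col]]
  bad <- !is.na(trend) & trend <= 0
  if (any(bad)) {
    warning(sum(bad), " cell-year(s) with non-positive trend set to missing",
            call. = FALSE)
    trend[bad] <- NA
  }
  out <- tibble::as_tibble(yields)
  out$anomaly <- (out$yield - trend) / trend * 100
  out
}
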