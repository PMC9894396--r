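#' Define a regular latitude-longitude grid
#'
#' All gridded artifacts in droughtsens live on a regular lat-lon grid with
#' cell-center registration: the first cell center sits half a resolution
#' step inside the stated edge. Longitudes use the \eqn{[-180, 180)}
#' convention; inputs on \eqn{[0, 360)} are rotated on read by
#' [read_gridded()].
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid edges in degrees.
#' @param resolution Cell size in degrees (default 0.5).
#'
#' @return A `grid_spec` object: a list with the edges, `resolution`,
#'   and derived cell counts `n_lat`, `n_lon`.
#' @examples
#' gs <- grid_spec(30, 40, -10, 0, resolution = 0.5)
#' gs$n_lat # 20
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max, resolution = 0.5) {
  stopifnot(resolution > 0, lat_max > lat_min, lon_max > lon_min)
  n_lat <- round((lat_max - lat_min) / resolution)
  n_lon <- round((lon_max - lon_min) / resolution)
  if (abs(n_lat * resolution - (lat_max - lat_min)) > 1e-8 ||
      abs(n_lon * resolution - (lon_max - lon_min)) > 1e-8) {
    stop("grid extent is not an integer multiple of the resolution",
         call. = FALSE)
  }
  if (lon_min < -180 - 1e-8 || lon_max > 180 + 1e-8) {
    stop("longitudes must lie in [-180, 180]", call. = FALSE)
  }
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max,
         resolution = resolution, n_lat = n_lat, n_lon = n_lon),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g deg, %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              x$resolution, x$n_lat, x$n_lon,
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell and columns `lat`, `lon`
#'   (cell centers, degrees), latitude varying slowest, both ascending.
#' @examples
#' grid_cells(grid_spec(0, 1, 0, 1, 0.5))
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  tidyr::expand_grid(lat = grid_lats(grid), lon = grid_lons(grid))
}

grid_lats <- function(grid) {
  grid$lat_min + grid$resolution * (seq_len(grid$n_lat) - 0.5)
}

grid_lons <- function(grid) {
  grid$lon_min + grid$resolution * (seq_len(grid$n_lon) - 0.5)
}

#' Recover the grid geometry from a gridded tibble
#'
#' Infers a [grid_spec()] from the unique `lat`/`lon` values of a long
#' gridded tibble. Coordinates must form a complete regular lattice.
#'
#' @param df A tibble with `lat` and `lon` columns (cell centers).
#' @return A `grid_spec`.
#' @export
infer_grid_spec <- function(df) {
  stopifnot(all(c("lat", "lon") %in% names(df)))
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  res_candidates <- c(diff(lats), diff(lons))
  if (length(res_candidates) == 0) {
    stop("cannot infer a grid from a single cell", call. = FALSE)
  }
  res <- min(res_candidates)
  if (any(abs(res_candidates - res) > 1e-6)) {
    stop("malformed grid: coordinate spacing is not uniform", call. = FALSE)
  }
  grid_spec(min(lats) - res / 2, max(lats) + res / 2,
            min(lons) - res / 2, max(lons) + res / 2,
            resolution = res)
}

# long (lat, lon, value) tibble -> matrix with rows = ascending lat,
# cols = ascending lon; missing cells become NA
raster_to_matrix <- function(df, value_col = "value", grid = NULL) {
  if (is.null(grid)) grid <- infer_grid_spec(df)
  lats <- grid_lats(grid)
  lons <- grid_lons(grid)
  m <- matrix(NA_real_, grid$n_lat, grid$n_lon)
  i <- as.integer(round((df$lat - grid$lat_min) / grid$resolution + 0.5))
  j <- as.integer(round((df$lon - grid$lon_min) / grid$resolution + 0.5))
  ok <- i >= 1 & i <= grid$n_lat & j >= 1 & j <= grid$n_lon &
    abs(df$lat - lats[pmax(pmin(i, grid$n_lat), 1)]) < grid$resolution / 4 &
    abs(df$lon - lons[pmax(pmin(j, grid$n_lon), 1)]) < grid$resolution / 4
  m[cbind(i[ok], j[ok])] <- df[[value_col]][ok]
  m
}

matrix_to_raster <- function(m, grid, value_col = "value") {
  out <- grid_cells(grid)
  out[[value_col]] <- as.vector(t(m)) # expand_grid: lat slow, lon fast
  out
}
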