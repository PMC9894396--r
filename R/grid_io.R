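#' Read a gridded NetCDF artifact into a long tibble
#'
#' Reads a CF-style single-variable NetCDF file (dimensions `lon`, `lat` and
#' optionally a time axis) into the package's long tibble form. Monthly time
#' axes with units `"days since YYYY-MM-DD"` or `"months since YYYY-MM"` are
#' decoded into integer `year` and `month` columns; an integer `year`
#' dimension is read as an annual grid; no time axis gives a static raster.
#' Longitudes on \eqn{[0, 360)} are rotated onto \eqn{[-180, 180)}.
#' File missing values become `NA`.
#'
#' @param path Path to a NetCDF file.
#' @param variable Variable name to read. If `NULL` and the file holds a
#'   single variable, that variable is read.
#' @return A tibble with columns `lat`, `lon`, (`year`, `month`) as
#'   applicable and the data column named after the variable's tibble
#'   column on write (stored in the `"value_col"` attribute; default
#'   `value`). Attributes: `units`, `variable`, and `dataset` if one was
#'   stored.
#' @seealso [write_gridded()], [regrid_bilinear()]
#' @export
read_gridded <- function(path, variable = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  have <- names(nc$var)
  if (is.null(variable)) {
    if (length(have) != 1) {
      stop("multiple variables in file; name one of: ",
           paste(have, collapse = ", "), call. = FALSE)
    }
    variable <- have
  }
  if (!variable %in% have) {
    stop("variable not found: ", variable, call. = FALSE)
  }

  lon <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  if (is.unsorted(lat) && is.unsorted(rev(lat))) {
    stop("malformed grid: latitude axis is not monotone", call. = FALSE)
  }
  if (is.unsorted(lon) && is.unsorted(rev(lon))) {
    stop("malformed grid: longitude axis is not monotone", call. = FALSE)
  }
  lon <- ifelse(lon >= 180, lon - 360, lon)

  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  dimnm <- vapply(nc$var[[variable]]$dim, function(d) d$name, character(1))

  out <- tidyr::expand_grid(lat = lat, lon = lon)
  time_cols <- NULL
  if ("time" %in% dimnm) {
    tdim <- nc$dim$time
    tu <- tdim$units
    tv <- as.vector(tdim$vals)
    if (grepl("^days since", tu)) {
      origin <- as.Date(sub("^days since\\s+(\\S+).*$", "\\1", tu))
      dates <- origin + round(tv)
      time_cols <- tibble::tibble(
        year = as.integer(format(dates, "%Y")),
        month = as.integer(format(dates, "%m"))
      )
    } else if (grepl("^months since", tu)) {
      anchor <- sub("^months since\\s+(\\d{4})-(\\d{2}).*$", "\\1 \\2", tu)
      ym <- as.integer(strsplit(anchor, " ")[[1]])
      idx <- ym[1] * 12L + (ym[2] - 1L) + as.integer(round(tv))
      time_cols <- tibble::tibble(year = idx %/% 12L, month = idx %% 12L + 1L)
    } else {
      stop("unsupported time units: ", tu, call. = FALSE)
    }
  } else if ("year" %in% dimnm) {
    time_cols <- tibble::tibble(year = as.integer(nc$dim$year$vals))
  }

  # ncdf4 returns dims in (lon, lat[, time]) order as written; column-major
  # traversal of a (lon, lat) slice is exactly lat-slow / lon-fast
  perm_val <- function(slice) as.vector(slice)
  if (is.null(time_cols)) {
    out$value <- perm_val(vals)
  } else {
    layers <- lapply(seq_len(nrow(time_cols)), function(k) {
      df <- out
      df$value <- perm_val(vals[, , k])
      dplyr::bind_cols(time_cols[rep(k, nrow(df)), , drop = FALSE], df)
    })
    out <- dplyr::bind_rows(layers)
    out <- out[, c("lat", "lon", names(time_cols), "value")]
  }

  value_col <- ncdf4::ncatt_get(nc, variable, "value_col")
  if (isTRUE(value_col$hasatt)) names(out)[names(out) == "value"] <- value_col$value
  units <- ncdf4::ncatt_get(nc, variable, "units")
  ds <- ncdf4::ncatt_get(nc, 0, "dataset")
  out <- dplyr::arrange(out, dplyr::across(dplyr::any_of(c("year", "month", "lat", "lon"))))
  attr(out, "units") <- if (isTRUE(units$hasatt)) units$value else ""
  attr(out, "variable") <- variable
  if (isTRUE(ds$hasatt)) {
    out <- dplyr::mutate(out, dataset = ds$value, .before = 1)
  }
  out
}

#' Write a gridded tibble to CF-style NetCDF
#'
#' The inverse of [read_gridded()]: a static raster (`lat`, `lon`, value),
#' annual grid (+`year`) or monthly grid (+`year`, `month`) tibble is
#' written as a single NetCDF variable with `units` and missing-value
#' attributes. The round trip preserves finite values bit-for-bit and the
#' missingness mask exactly.
#'
#' @param df Gridded tibble. A `dataset` column is allowed if it holds a
#'   single label (stored as a global attribute); write ensemble members to
#'   separate files.
#' @param path Output path.
#' @param variable NetCDF variable name (default: the value column's name).
#' @param units Units string attribute (default taken from `attr(df, "units")`).
#' @return `path`, invisibly.
#' @export
write_gridded <- function(df, path, variable = NULL, units = NULL) {
  df <- tibble::as_tibble(df)
  if ("dataset" %in% names(df)) {
    ds <- unique(df$dataset)
    if (length(ds) > 1) {
      stop("write one ensemble member per file (", length(ds),
           " dataset labels found)", call. = FALSE)
    }
    df$dataset <- NULL
  } else ds <- NULL

  coord_cols <- intersect(c("lat", "lon", "year", "month"), names(df))
  value_col <- setdiff(names(df), coord_cols)
  if (length(value_col) != 1) {
    stop("expected exactly one value column, got: ",
         paste(value_col, collapse = ", "), call. = FALSE)
  }
  if (is.null(variable)) variable <- value_col
  if (is.null(units)) units <- attr(df, "units") %||% ""

  grid <- infer_grid_spec(df)
  lats <- grid_lats(grid)
  lons <- grid_lons(grid)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)

  monthly <- all(c("year", "month") %in% names(df))
  annual <- "year" %in% names(df) && !monthly
  missval <- 1e32

  if (monthly) {
    key <- dplyr::distinct(df[, c("year", "month")])
    key <- dplyr::arrange(key, .data$year, .data$month)
    origin <- as.Date(sprintf("%d-01-01", min(key$year)))
    dates <- as.Date(sprintf("%d-%02d-15", key$year, key$month))
    dim_t <- ncdf4::ncdim_def("time", paste("days since", format(origin)),
                              as.numeric(dates - origin), unlim = FALSE)
    dims <- list(dim_lon, dim_lat, dim_t)
  } else if (annual) {
    years <- sort(unique(df$year))
    dim_t <- ncdf4::ncdim_def("year", "year", as.integer(years),
                              create_dimvar = TRUE)
    dims <- list(dim_lon, dim_lat, dim_t)
    key <- tibble::tibble(year = years)
  } else {
    dims <- list(dim_lon, dim_lat)
    key <- NULL
  }

  var <- ncdf4::ncvar_def(variable, units, dims, missval = missval,
                          prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)

  layer_array <- function(layer) {
    m <- raster_to_matrix(layer, value_col = value_col, grid = grid)
    a <- t(m) # -> lon x lat
    a[is.na(a)] <- missval
    a
  }
  if (is.null(key)) {
    ncdf4::ncvar_put(nc, var, layer_array(df))
  } else {
    arr <- array(missval, c(grid$n_lon, grid$n_lat, nrow(key)))
    if (monthly) {
      id <- match(df$year * 12L + df$month, key$year * 12L + key$month)
    } else {
      id <- match(df$year, key$year)
    }
    pieces <- split(seq_len(nrow(df)), factor(id, levels = seq_len(nrow(key))))
    for (k in seq_len(nrow(key))) {
      if (length(pieces[[k]]) > 0) {
        arr[, , k] <- layer_array(df[pieces[[k]], , drop = FALSE])
      }
    }
    ncdf4::ncvar_put(nc, var, arr)
  }
  ncdf4::ncatt_put(nc, variable, "value_col", value_col)
  if (!is.null(ds)) ncdf4::ncatt_put(nc, 0, "dataset", as.character(ds))
  invisible(path)
}

#' Regrid a gridded tibble by bilinear interpolation
#'
#' Every target cell center receives the bilinear interpolant of the four
#' surrounding source cell centers. Target cells outside the source
#' cell-center hull, or with any missing contributor among the four, are
#' missing: interpolation never fabricates data at cropland edges. Annual
#' and monthly grids are regridded layer by layer.
#'
#' @param df Source gridded tibble (static, annual or monthly).
#' @param target A [grid_spec()] describing the output grid.
#' @return A tibble of the same kind on the target grid.
#' @examples
#' src <- grid_cells(grid_spec(0, 4, 0, 4, 1))
#' src$value <- 2 * src$lat + 3 * src$lon # affine: reproduced exactly
#' out <- regrid_bilinear(src, grid_spec(1, 3, 1, 3, 0.5))
#' all.equal(out$value, 2 * out$lat + 3 * out$lon)
#' @export
regrid_bilinear <- function(df, target) {
  regrid_with(df, target, function(m, src_grid) {
    tgt <- grid_cells(target)
    src_lats <- grid_lats(src_grid)
    src_lons <- grid_lons(src_grid)
    inside <- tgt$lat >= src_lats[1] & tgt$lat <= src_lats[length(src_lats)] &
      tgt$lon >= src_lons[1] & tgt$lon <= src_lons[length(src_lons)]
    if (!any(inside)) stop("no overlap between source and target grids",
                           call. = FALSE)
    v <- rep(NA_real_, nrow(tgt))
    v[inside] <- pracma::interp2(src_lons, src_lats, m,
                                 tgt$lon[inside], tgt$lat[inside],
                                 method = "linear")
    v
  })
}

#' Regrid a gridded tibble by nearest neighbour
#'
#' For categorical or near-categorical rasters (e.g. the harvest-month crop
#' calendar) where interpolation between category codes is meaningless.
#'
#' @inheritParams regrid_bilinear
#' @return A tibble of the same kind on the target grid.
#' @export
regrid_nearest <- function(df, target) {
  regrid_with(df, target, function(m, src_grid) {
    tgt <- grid_cells(target)
    src_lats <- grid_lats(src_grid)
    src_lons <- grid_lons(src_grid)
    half <- src_grid$resolution / 2
    i <- findInterval(tgt$lat, src_lats + src_grid$resolution / 2) + 1L
    j <- findInterval(tgt$lon, src_lons + src_grid$resolution / 2) + 1L
    ok <- tgt$lat >= src_lats[1] - half & tgt$lat <= src_lats[length(src_lats)] + half &
      tgt$lon >= src_lons[1] - half & tgt$lon <= src_lons[length(src_lons)] + half
    if (!any(ok)) stop("no overlap between source and target grids",
                       call. = FALSE)
    i <- pmax(pmin(i, src_grid$n_lat), 1L)
    j <- pmax(pmin(j, src_grid$n_lon), 1L)
    v <- m[cbind(i, j)]
    v[!ok] <- NA_real_
    v
  })
}

regrid_with <- function(df, target, layer_fun) {
  stopifnot(inherits(target, "grid_spec"))
  df <- tibble::as_tibble(df)
  coord_cols <- intersect(c("lat", "lon", "year", "month", "dataset"), names(df))
  value_col <- setdiff(names(df), coord_cols)
  if (length(value_col) != 1) {
    stop("expected exactly one value column", call. = FALSE)
  }
  src_grid <- infer_grid_spec(df)
  group_cols <- intersect(c("dataset", "year", "month"), names(df))

  one_layer <- function(layer) {
    m <- raster_to_matrix(layer, value_col = value_col, grid = src_grid)
    out <- grid_cells(target)
    out[[value_col]] <- layer_fun(m, src_grid)
    out
  }
  if (length(group_cols) == 0) {
    out <- one_layer(df)
  } else {
    out <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
      dplyr::group_modify(~ one_layer(.x)) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c("lat", "lon", group_cols, value_col)))
  }
  attr(out, "units") <- attr(df, "units")
  out
}
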