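#' Simulate an ensemble of gridded monthly precipitation
#'
#' Draws monthly precipitation from the same family the SPI standardization
#' fits: for calendar month m, a value is exactly zero with probability
#' `zero_prob[m]` and otherwise Gamma(`shape[m]`, scale = `scale[m]`).
#' Ensemble members share one latent draw per cell-month plus independent
#' Gaussian noise truncated at zero, so members correlate the way real
#' precipitation products do.
#'
#' @param grid A [grid_spec()].
#' @param years Length-2 integer vector `c(start, end)` (calendar years).
#' @param n_datasets Number of ensemble members (default 8, the usual size
#'   of a multi-product precipitation ensemble).
#' @param shape,scale Gamma shape and scale (mm) per calendar month; scalars
#'   or length-12 vectors. Defaults give a mild seasonal cycle around a
#'   75 mm/month mean.
#' @param zero_prob Probability of an exactly dry month, scalar or length-12,
#'   each in \eqn{[0, 0.9]}.
#' @param noise_sd Standard deviation (mm) of the independent inter-member
#'   noise. `0` makes all members identical.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A tibble with columns `dataset`, `lat`, `lon`, `year`, `month`,
#'   `precip` (mm/month).
#' @export
simulate_precipitation <- function(grid, years = c(1981, 2016), n_datasets = 8,
                                   shape = 3 + 1.5 * sinpi((1:12 - 1) / 6),
                                   scale = 25, zero_prob = 0.05,
                                   noise_sd = 5, seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"), length(years) == 2,
            years[2] >= years[1], n_datasets >= 1, noise_sd >= 0)
  shape <- rep_len(shape, 12)
  scale <- rep_len(scale, 12)
  zero_prob <- rep_len(zero_prob, 12)
  if (any(shape <= 0) || any(scale <= 0)) {
    stop("invalid gamma parameters: shape and scale must be positive",
         call. = FALSE)
  }
  if (any(zero_prob < 0 | zero_prob > 0.9)) {
    stop("zero_prob must lie in [0, 0.9]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  cells <- grid_cells(grid)
  yrs <- seq(years[1], years[2])
  frame <- tidyr::expand_grid(cells, year = yrs, month = 1:12)
  n <- nrow(frame)
  m <- frame$month
  dry <- stats::runif(n) < zero_prob[m]
  latent <- ifelse(dry, 0,
                   stats::rgamma(n, shape = shape[m], scale = scale[m]))

  purrr::map_dfr(seq_len(n_datasets), function(d) {
    val <- if (noise_sd > 0) {
      pmax(latent + stats::rnorm(n, sd = noise_sd), 0)
    } else latent
    dplyr::bind_cols(
      tibble::tibble(dataset = sprintf("synth%02d", d)),
      frame, tibble::tibble(precip = val)
    )
  })
}

#' Simulate a harvest-month crop calendar
#'
#' @param grid A [grid_spec()].
#' @param mode `"constant"` (every cell harvests in `month`) or
#'   `"latitudinal"` (harvest month varies smoothly with latitude across
#'   the grid, mimicking the poleward shift of harvest dates).
#' @param month Harvest month for `mode = "constant"`.
#' @return A static raster tibble `lat`, `lon`, `harvest_month` (integer
#'   1-12).
#' @export
simulate_crop_calendar <- function(grid, mode = c("constant", "latitudinal"),
                                   month = 9) {
  mode <- match.arg(mode)
  stopifnot(month %in% 1:12)
  out <- grid_cells(grid)
  if (mode == "constant") {
    out$harvest_month <- as.integer(month)
  } else {
    rng <- range(out$lat)
    frac <- if (diff(rng) == 0) 0.5 else (out$lat - rng[1]) / diff(rng)
    out$harvest_month <- as.integer(pmin(12, pmax(1, round(1 + 11 * frac))))
  }
  out
}

#' Simulate annual yields with a planted drought sensitivity
#'
#' Generates the inverse of the analysis model: yields follow a smooth
#' positive trend perturbed multiplicatively by a planted drought response,
#' `Y_t = trend_t * (1 + (beta * DI_t + e_t) / 100)` with `e_t ~ N(0,
#' sigma^2)` and `DI_t` taken as 0 in non-drought (missing-DI) years. Yields
#' are floored at zero. Because the true trend is returned alongside the
#' yields, downstream recovery tests can separate trend-estimation error
#' from regression error.
#'
#' @param di Drought-index tibble (`lat`, `lon`, `year`, `di`), as from
#'   [compute_di()]; `NA` means a non-drought year.
#' @param beta Planted sensitivity (percent yield anomaly per unit drought
#'   index): a scalar or a tibble `lat`, `lon`, `beta`.
#' @param trend Trend family: `"linear"`, `"logistic"` or `"piecewise"`.
#' @param base Trend level (t/ha) in the first year.
#' @param growth Trend slope (t/ha per year; for `"logistic"`, the total
#'   rise, and for `"piecewise"`, the pre-break slope with the post-break
#'   slope halved).
#' @param sigma Anomaly noise standard deviation (percent).
#' @param seed Integer seed.
#' @return A tibble `lat`, `lon`, `year`, `yield`, `trend_true` (t/ha).
#' @export
simulate_yields <- function(di, beta, trend = c("linear", "logistic", "piecewise"),
                            base = 5, growth = 0.05, sigma = 3, seed = NULL) {
  trend <- match.arg(trend)
  stopifnot(all(c("lat", "lon", "year", "di") %in% names(di)), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)

  out <- tibble::as_tibble(di)
  yrs <- sort(unique(out$year))
  t0 <- min(yrs)
  tt <- out$year - t0
  span <- max(out$year) - t0
  out$trend_true <- switch(
    trend,
    linear = base + growth * tt,
    logistic = base + growth * stats::plogis((tt - span / 2) / max(span / 8, 1)),
    piecewise = base + ifelse(tt <= span / 2, growth * tt,
                              growth * span / 2 + 0.5 * growth * (tt - span / 2))
  )
  if (any(out$trend_true <= 0)) {
    stop("invalid trend: expected yield must stay positive", call. = FALSE)
  }

  if (is.data.frame(beta)) {
    stopifnot(all(c("lat", "lon", "beta") %in% names(beta)))
    out <- dplyr::left_join(out, beta[, c("lat", "lon", "beta")],
                            by = c("lat", "lon"))
    if (anyNA(out$beta)) {
      stop("beta raster does not cover every cell of `di`", call. = FALSE)
    }
  } else {
    out$beta <- beta
  }

  di0 <- ifelse(is.na(out$di), 0, out$di)
  eps <- if (sigma > 0) stats::rnorm(nrow(out), sd = sigma) else 0
  out$yield <- pmax(out$trend_true * (1 + (out$beta * di0 + eps) / 100), 0)
  out[, c("lat", "lon", "year", "yield", "trend_true")]
}

#' Names of the 22 determinant rasters
#'
#' The standard determinant set spans seven classes: climate (mean annual
#' precipitation, potential evapotranspiration, temperature), terrain
#' (elevation, slope), soil (hydraulic conductivity, clay, organic carbon,
#' acidity, water-holding capacity), irrigation (area equipped, actually
#' irrigated, groundwater, non-conventional sources), production (growing
#' season length, harvested area), fertilizer (N, P, K application rates)
#' and socioeconomic (GDP, GDP per capita, population density).
#'
#' @return Character vector of 22 predictor names.
#' @export
determinant_names <- function() {
  c("precipitation", "pet", "temperature",
    "elevation", "slope",
    "hydraulic_conductivity", "clay", "organic_carbon", "acidity",
    "water_holding_capacity",
    "aei", "aai", "aei_groundwater", "aei_nonconventional",
    "growing_season_length", "harvested_area",
    "nitrogen_rate", "phosphorus_rate", "potassium_rate",
    "gdp", "gdp_per_capita", "population_density")
}

#' Default determinant-to-sensitivity links
#'
#' Two predictors carry signal and the remaining twenty are pure-noise
#' controls: mean annual precipitation enters linearly (wetter climates
#' damp drought losses) and soil water-holding capacity through a saturating
#' `tanh` (buffering that levels off). Every other link is `"none"`.
#'
#' @return Named list of link specifications, one per determinant; each is
#'   `list(type = "none")`, `list(type = "linear", coef = )`,
#'   `list(type = "tanh", amplitude = )` or `list(type = "cubic", coef = )`.
#' @export
default_determinant_links <- function() {
  links <- stats::setNames(
    rep(list(list(type = "none")), length(determinant_names())),
    determinant_names()
  )
  links$precipitation <- list(type = "linear", coef = 5)
  links$water_holding_capacity <- list(type = "tanh", amplitude = 4)
  links
}

#' Simulate determinant rasters with a known link to sensitivity
#'
#' Each predictor is a spatially smooth standardized Gaussian random field
#' (white noise blurred with a Gaussian kernel, default scale 3 cells). The
#' true sensitivity field is composed as `beta0 + sum_j link_j(x_j) + eta`
#' with `eta ~ N(0, noise_sd^2)`, so attribution methods can be scored
#' against known importance ranks and known monotone shapes.
#'
#' @param grid A [grid_spec()].
#' @param links Named list of link specs (see
#'   [default_determinant_links()]); at least one must be `"none"`.
#' @param beta0 Baseline sensitivity (percent per unit drought index;
#'   negative = drought loss).
#' @param noise_sd Standard deviation of the unexplained component of the
#'   true sensitivity field.
#' @param smoothness Gaussian blur sigma in cells.
#' @param seed Integer seed.
#' @return A list with `predictors` (long tibble `lat`, `lon`, `predictor`,
#'   `value`) and `beta` (tibble `lat`, `lon`, `beta`, the planted truth).
#' @export
simulate_predictors <- function(grid, links = default_determinant_links(),
                                beta0 = -8, noise_sd = 2, smoothness = 3,
                                seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"), noise_sd >= 0)
  nms <- names(links)
  if (is.null(nms) || anyDuplicated(nms) > 0) {
    stop("links must be a uniquely named list", call. = FALSE)
  }
  types <- vapply(links, function(l) l$type, character(1))
  known <- c("none", "linear", "tanh", "cubic")
  if (any(!types %in% known)) {
    stop("unknown link id: ", paste(setdiff(types, known), collapse = ", "),
         call. = FALSE)
  }
  if (!any(types == "none")) {
    stop("at least one predictor must have link \"none\" as a noise control",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  cells <- grid_cells(grid)
  contrib <- 0
  fields <- purrr::map(nms, function(nm) {
    f <- simulate_smooth_field(grid, sigma = smoothness)
    lk <- links[[nm]]
    g <- switch(lk$type,
                none = 0,
                linear = lk$coef * f,
                tanh = lk$amplitude * tanh(f),
                cubic = lk$coef * f^3)
    contrib <<- contrib + g
    f
  })
  names(fields) <- nms

  predictors <- purrr::imap_dfr(fields, function(f, nm) {
    dplyr::bind_cols(cells, tibble::tibble(predictor = nm, value = f))
  })[, c("lat", "lon", "predictor", "value")]

  eta <- if (noise_sd > 0) stats::rnorm(nrow(cells), sd = noise_sd) else 0
  beta <- dplyr::bind_cols(cells,
                           tibble::tibble(beta = beta0 + contrib + eta))
  list(predictors = predictors, beta = beta)
}

# Smooth standardized random field: white noise blurred with a separable
# Gaussian kernel (reflecting edges), then centred and scaled to unit sd.
simulate_smooth_field <- function(grid, sigma = 3) {
  m <- matrix(stats::rnorm(grid$n_lat * grid$n_lon), grid$n_lat, grid$n_lon)
  m <- gaussian_blur(m, sigma)
  v <- as.vector(t(m)) # lat slow, lon fast: matches grid_cells()
  if (stats::sd(v) > 0) v <- (v - mean(v)) / stats::sd(v)
  v
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  reflect_pad <- function(x, h) {
    n <- length(x)
    c(x[pmin(h:1, n)], x, x[pmax(n - 1:h + 1 - 0, 1)])
  }
  conv1 <- function(x) {
    xp <- reflect_pad(x, half)
    stats::filter(xp, k, sides = 2)[(half + 1):(half + length(x))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}
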