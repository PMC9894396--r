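#' Build a pipeline configuration
#'
#' Collects every knob of the drought-sensitivity pipeline with defaults
#' matching the analysis' standard choices: 0.5 degree grid, 1981-2016
#' window, 9-month SPI calibrated on the full window, two-tailed P < 0.05,
#' 500 trees, >80% irrigated threshold. The default grid is a desk-scale
#' 20 x 20 tile; the method is resolution-agnostic.
#'
#' @param grid A [grid_spec()].
#' @param years `c(start, end)` analysis window (calendar years).
#' @param crops Character vector of crop labels (processed independently).
#' @param n_datasets Number of precipitation ensemble members (synthetic
#'   mode).
#' @param timescale SPI accumulation window k in months.
#' @param clip SPI clip bound.
#' @param calibration Gamma-fit window `c(start, end)`; `NULL` = `years`.
#' @param span,degree Local-polynomial detrending controls.
#' @param trend_method `"loess"` (estimate the trend) or `"known"` (use the
#'   generator's true trend; synthetic mode only — isolates the
#'   drought-regression chain from trend-estimation error).
#' @param n_min Minimum drought years per cell for a sensitivity fit.
#' @param di_policy `"drop"` or `"zero"` (see [fit_sensitivity()]).
#' @param irrigation_threshold Irrigated-class threshold on the fraction.
#' @param bin_width Sensitivity bin width (percent per unit DI).
#' @param n_trees Random-forest size.
#' @param pdp_predictors Predictors whose partial dependence is computed.
#' @param top_k Size of the top-determinants report.
#' @param input `"synthetic"` or `"files"`.
#' @param files For `input = "files"`: named list with `precip` (vector of
#'   NetCDF paths, one per ensemble member), `calendar`, `yields`, and
#'   optionally `predictors` (named vector of paths), `harvested_area`,
#'   `irrigated_fraction`.
#' @param synthetic Named list of generator settings overriding the
#'   defaults: `beta0`, `sigma` (yield noise sd, percent), `noise_sd`
#'   (unexplained sensitivity sd), `links`, `smoothness`, `shape`, `scale`,
#'   `zero_prob`, `precip_noise_sd`, `trend`, `base`, `growth`,
#'   `harvest_mode`, `harvest_month`.
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid = grid_spec(30, 40, -10, 0, 0.5),
                            years = c(1981, 2016),
                            crops = "maize",
                            n_datasets = 8,
                            timescale = 9,
                            clip = 3.09,
                            calibration = NULL,
                            span = 0.67,
                            degree = 2,
                            trend_method = c("loess", "known"),
                            n_min = 10,
                            di_policy = c("drop", "zero"),
                            irrigation_threshold = 0.8,
                            bin_width = 5,
                            n_trees = 500,
                            pdp_predictors = c("precipitation",
                                               "water_holding_capacity"),
                            top_k = 6,
                            input = c("synthetic", "files"),
                            files = list(),
                            synthetic = list(),
                            seed = 42) {
  syn_defaults <- list(beta0 = -8, sigma = 3, noise_sd = 2,
                       links = default_determinant_links(), smoothness = 3,
                       shape = 3 + 1.5 * sinpi((1:12 - 1) / 6), scale = 25,
                       zero_prob = 0.05, precip_noise_sd = 5,
                       trend = "linear", base = 5, growth = 0.05,
                       harvest_mode = "latitudinal", harvest_month = 9)
  syn <- utils::modifyList(syn_defaults, synthetic)
  structure(
    list(grid = grid, years = years, crops = crops, n_datasets = n_datasets,
         timescale = timescale, clip = clip,
         calibration = calibration %||% years,
         span = span, degree = degree,
         trend_method = match.arg(trend_method),
         n_min = n_min, di_policy = match.arg(di_policy),
         irrigation_threshold = irrigation_threshold, bin_width = bin_width,
         n_trees = n_trees, pdp_predictors = pdp_predictors, top_k = top_k,
         input = match.arg(input), files = files, synthetic = syn,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] arguments; `grid` is a mapping with
#' `lat_min`, `lat_max`, `lon_min`, `lon_max`, `resolution`.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$grid)) raw$grid <- do.call(grid_spec, raw$grid)
  known <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[known])
}

#' Validate a pipeline configuration
#'
#' Reports human-readable violations (ranges, cross-field consistency,
#' missing input files) without stopping.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of issues; empty when the config is valid.
#' @export
validate_config <- function(config) {
  issues <- character()
  note <- function(msg) issues <<- c(issues, msg)
  if (!inherits(config$grid, "grid_spec")) note("grid must be a grid_spec")
  if (length(config$years) != 2 || config$years[2] < config$years[1]) {
    note("years must be c(start, end) with end >= start")
  }
  n_years <- diff(config$years) + 1
  if (config$timescale < 1) note("timescale must be >= 1")
  if (config$timescale > 12 * n_years) {
    note("timescale exceeds the monthly record length")
  }
  if (!(config$span > 0 && config$span <= 1)) note("span must be in (0, 1]")
  if (!config$degree %in% 1:2) note("degree must be 1 or 2")
  if (config$n_min < 3) note("n_min must be >= 3")
  if (n_years < config$n_min) {
    note(sprintf(paste0("a %d-year window cannot provide the n_min = %d ",
                        "drought years required per cell"),
                 n_years, config$n_min))
  }
  if (config$bin_width <= 0) note("bin_width must be positive")
  if (config$n_trees < 1) note("n_trees must be >= 1")
  if (config$irrigation_threshold < 0 || config$irrigation_threshold > 1) {
    note("irrigation_threshold must lie in [0, 1]")
  }
  if (config$input == "files") {
    needed <- c("precip", "calendar", "yields")
    missing_keys <- setdiff(needed, names(config$files))
    if (length(missing_keys) > 0) {
      note(paste("files mode needs paths for:",
                 paste(missing_keys, collapse = ", ")))
    }
    paths <- unlist(config$files, use.names = FALSE)
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0) {
      note(paste("missing input file(s):", paste(absent, collapse = ", ")))
    }
    if (config$trend_method == "known") {
      note("trend_method \"known\" requires synthetic input")
    }
  }
  issues
}

#' Run the full drought-sensitivity pipeline
#'
#' Executes generate/load -> SPI -> drought index -> yields -> detrend ->
#' sensitivity -> summaries -> attribution in dependency order, writes all
#' artifacts (NetCDF rasters, CSV tables, JSON summary) under `out_dir`,
#' and returns a manifest with per-stage wall times, warning counts and
#' file hashes. Re-running with an identical config reproduces identical
#' hashes. A stage failure aborts with the failing stage named, after
#' writing the partial manifest.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return A `pipeline_manifest`: list with `config`, `stages` (tibble of
#'   timings and warning counts), `files` (tibble of artifact paths and MD5
#'   hashes), `results` (in-memory key outputs) and `summary` (the list
#'   also written to `summary.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("droughtsens-run-")) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_config(config)
  if (length(issues) > 0) {
    stop("invalid config:\n- ", paste(issues, collapse = "\n- "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- tibble::tibble(stage = character(), seconds = numeric(),
                           warnings = integer())
  files <- tibble::tibble(artifact = character(), path = character(),
                          md5 = character())

  stage <- function(name, fun) {
    n_warn <- 0L
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest <- make_manifest(config, stages, files, partial = name)
        write_manifest(manifest, out_dir)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    stages <<- dplyr::bind_rows(stages, tibble::tibble(
      stage = name, seconds = proc.time()[["elapsed"]] - t0,
      warnings = n_warn))
    res
  }
  keep <- function(artifact, path) {
    files <<- dplyr::bind_rows(files, tibble::tibble(
      artifact = artifact, path = path,
      md5 = unname(tools::md5sum(path))))
  }
  syn <- config$synthetic
  seed0 <- config$seed

  # ---- inputs -------------------------------------------------------------
  inputs <- stage("inputs", function() {
    if (config$input == "synthetic") {
      precip <- simulate_precipitation(
        config$grid, config$years, config$n_datasets,
        shape = syn$shape, scale = syn$scale, zero_prob = syn$zero_prob,
        noise_sd = syn$precip_noise_sd, seed = seed0 + 1L)
      calendar <- simulate_crop_calendar(config$grid, syn$harvest_mode,
                                         month = syn$harvest_month)
      set.seed(seed0 + 2L)
      pred <- simulate_predictors(config$grid, links = syn$links,
                                  beta0 = syn$beta0, noise_sd = syn$noise_sd,
                                  smoothness = syn$smoothness)
      area <- grid_cells(config$grid)
      area$harvested_area <- 1000 * stats::plogis(
        simulate_smooth_field(config$grid, syn$smoothness))
      frac <- grid_cells(config$grid)
      frac$irrigated_fraction <- stats::plogis(
        2 * simulate_smooth_field(config$grid, syn$smoothness))
      list(precip = precip, calendar = calendar,
           predictors = pred$predictors, beta_true = pred$beta,
           harvested_area = area, irrigated_fraction = frac, yields = NULL)
    } else {
      precip <- purrr::imap_dfr(config$files$precip, function(p, i) {
        df <- read_gridded(p)
        if (!"dataset" %in% names(df)) df$dataset <- sprintf("member%02d", i)
        names(df)[!names(df) %in% c("dataset", "lat", "lon", "year", "month")] <- "precip"
        df
      })
      read_static <- function(key) {
        if (is.null(config$files[[key]])) return(NULL)
        read_gridded(config$files[[key]])
      }
      predictors <- NULL
      if (!is.null(config$files$predictors)) {
        predictors <- purrr::imap_dfr(config$files$predictors, function(p, nm) {
          df <- read_gridded(p)
          vc <- setdiff(names(df), c("lat", "lon"))
          tibble::tibble(lat = df$lat, lon = df$lon, predictor = nm,
                         value = df[[vc]])
        })
      }
      yields <- read_gridded(config$files$yields)
      names(yields)[!names(yields) %in% c("lat", "lon", "year")] <- "yield"
      list(precip = precip, calendar = read_static("calendar"),
           predictors = predictors, beta_true = NULL,
           harvested_area = read_static("harvested_area"),
           irrigated_fraction = read_static("irrigated_fraction"),
           yields = yields)
    }
  })
  p_cal <- file.path(out_dir, "crop_calendar.nc")
  write_gridded(inputs$calendar, p_cal, units = "month")
  keep("crop_calendar", p_cal)

  # ---- SPI and drought index ---------------------------------------------
  spi_ens <- stage("spi", function() {
    spi <- compute_spi(inputs$precip, k = config$timescale,
                       calibration = config$calibration, clip = config$clip)
    ensemble_spi(spi)
  })
  p_spi <- file.path(out_dir, "spi_ensemble.nc")
  write_gridded(spi_ens, p_spi, variable = "spi", units = "1")
  keep("spi_ensemble", p_spi)

  di <- stage("drought_index", function() compute_di(spi_ens, inputs$calendar))
  p_di <- file.path(out_dir, "drought_index.nc")
  write_gridded(di[, c("lat", "lon", "year", "di")], p_di, units = "1")
  keep("drought_index", p_di)

  # ---- yields and anomalies ----------------------------------------------
  yields <- stage("yields", function() {
    if (config$input == "synthetic") {
      simulate_yields(di, beta = inputs$beta_true, trend = syn$trend,
                      base = syn$base, growth = syn$growth,
                      sigma = syn$sigma, seed = seed0 + 3L)
    } else inputs$yields
  })
  anomalies <- stage("detrend", function() {
    if (config$trend_method == "known") {
      anomaly_percent(yields, trend_col = "trend_true")
    } else {
      anomaly_percent(fit_yield_trend(yields, span = config$span,
                                      degree = config$degree))
    }
  })
  p_anom <- file.path(out_dir, "yield_anomaly.nc")
  write_gridded(anomalies[, c("lat", "lon", "year", "anomaly")], p_anom,
                units = "percent")
  keep("yield_anomaly", p_anom)

  # ---- sensitivity --------------------------------------------------------
  records <- stage("sensitivity", function() {
    sensitivity_map(anomalies, di, n_min = config$n_min,
                    di_policy = config$di_policy)
  })
  p_beta <- file.path(out_dir, "beta.nc")
  write_gridded(records[, c("lat", "lon", "beta")], p_beta,
                units = "percent per DI")
  keep("beta", p_beta)
  p_p <- file.path(out_dir, "p_value.nc")
  write_gridded(records[, c("lat", "lon", "p")], p_p, variable = "p",
                units = "1")
  keep("p_value", p_p)
  p_cells <- file.path(out_dir, "cells.csv")
  utils::write.csv(records, p_cells, row.names = FALSE)
  keep("cells", p_cells)

  summaries <- stage("summaries", function() {
    s <- summarize_sensitivity(records, weighting = "cells")
    bins <- NULL
    classes <- NULL
    if (!is.null(inputs$harvested_area)) {
      s <- dplyr::bind_rows(
        s, summarize_sensitivity(records, inputs$harvested_area,
                                 weighting = "area"))
    }
    if (!is.null(inputs$irrigated_fraction) &&
        !is.null(inputs$harvested_area)) {
      classes <- classify_irrigation(inputs$irrigated_fraction,
                                     threshold = config$irrigation_threshold)
      bins <- binned_area_share(records, classes, inputs$harvested_area,
                                bin_width = config$bin_width)
    }
    list(table = s, classes = classes, bins = bins)
  })
  if (!is.null(summaries$bins)) {
    p_bins <- file.path(out_dir, "area_share_bins.csv")
    utils::write.csv(summaries$bins, p_bins, row.names = FALSE)
    keep("area_share_bins", p_bins)
  }

  # ---- attribution --------------------------------------------------------
  attribution <- stage("attribution", function() {
    if (is.null(inputs$predictors)) return(NULL)
    features <- build_feature_table(records, inputs$predictors,
                                    crop = config$crops[1])
    fit <- fit_attribution(features, n_trees = config$n_trees,
                           seed = seed0 + 4L)
    imp <- attribution_importance(fit)
    pdp <- partial_dependence(
      fit, intersect(config$pdp_predictors, fit$predictors))
    list(fit = fit, importance = imp, pdp = pdp)
  })
  if (!is.null(attribution)) {
    p_imp <- file.path(out_dir, "importance.csv")
    utils::write.csv(attribution$importance, p_imp, row.names = FALSE)
    keep("importance", p_imp)
    p_pdp <- file.path(out_dir, "partial_dependence.csv")
    utils::write.csv(attribution$pdp, p_pdp, row.names = FALSE)
    keep("partial_dependence", p_pdp)
  }

  # ---- recovery metrics (synthetic ground truth only) ---------------------
  recovery <- stage("recovery", function() {
    if (is.null(inputs$beta_true)) return(NULL)
    cmp <- dplyr::inner_join(
      dplyr::filter(records, is.na(.data$flag)),
      stats::setNames(inputs$beta_true, c("lat", "lon", "beta_true")),
      by = c("lat", "lon"))
    tcrit <- stats::qt(0.975, pmax(cmp$n - 2, 1))
    covered <- cmp$beta_true >= cmp$beta - tcrit * cmp$se &
      cmp$beta_true <= cmp$beta + tcrit * cmp$se
    list(n_evaluated = nrow(cmp),
         max_abs_error = max(abs(cmp$beta - cmp$beta_true)),
         mean_bias = mean(cmp$beta - cmp$beta_true),
         rmse = sqrt(mean((cmp$beta - cmp$beta_true)^2)),
         correlation = stats::cor(cmp$beta, cmp$beta_true),
         ci95_coverage = 100 * mean(covered))
  })

  summary_list <- list(
    sensitivity = as.list(summaries$table[1, ]),
    sensitivity_by_weighting = summaries$table,
    attribution = if (!is.null(attribution)) {
      c(as.list(glance(attribution$fit)),
        list(top = utils::head(attribution$importance$predictor,
                               config$top_k)))
    },
    recovery = recovery
  )
  p_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_list, p_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  keep("summary", p_sum)

  manifest <- make_manifest(config, stages, files, partial = NULL)
  manifest$results <- list(records = records, summaries = summaries$table,
                           bins = summaries$bins,
                           attribution = attribution, recovery = recovery)
  manifest$summary <- summary_list
  write_manifest(manifest, out_dir)
  manifest
}

make_manifest <- function(config, stages, files, partial = NULL) {
  structure(
    list(config = config, stages = stages, files = files,
         failed_stage = partial, results = NULL, summary = NULL),
    class = "pipeline_manifest"
  )
}

write_manifest <- function(manifest, out_dir) {
  cfg <- manifest$config
  cfg$grid <- unclass(cfg$grid)
  cfg$synthetic$links <- NULL # functions/structures not meaningful in JSON
  jsonlite::write_json(
    list(config = unclass(cfg), stages = manifest$stages,
         files = manifest$files, failed_stage = manifest$failed_stage),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>", nrow(x$stages), "stages,",
      nrow(x$files), "artifacts\n")
  if (!is.null(x$failed_stage)) cat("  FAILED at stage:", x$failed_stage, "\n")
  cat(sprintf("  total wall time: %.1f s\n", sum(x$stages$seconds)))
  if (!is.null(x$summary$recovery)) {
    cat(sprintf("  beta recovery: max abs err %.3g, 95%% CI coverage %.1f%%\n",
                x$summary$recovery$max_abs_error,
                x$summary$recovery$ci95_coverage))
  }
  invisible(x)
}
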