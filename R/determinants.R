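#' Assemble the determinant feature table
#'
#' One row per grid cell with a finite sensitivity estimate and all
#' predictors finite (complete cases only); no significance filter is
#' applied — attribution uses every evaluable cell. Dropped-row counts are
#' attached by cause.
#'
#' @param beta_map Sensitivity records from [sensitivity_map()] (uses
#'   `beta`), or any tibble `lat`, `lon`, `beta`.
#' @param predictors Long predictor tibble `lat`, `lon`, `predictor`,
#'   `value` (see [simulate_predictors()]).
#' @param crop Optional crop label stored in a `crop` column.
#' @return Tibble `lat`, `lon` (, `crop`), `beta`, one column per
#'   predictor; attributes `n_dropped_beta` and `n_dropped_predictor`.
#' @export
build_feature_table <- function(beta_map, predictors, crop = NULL) {
  stopifnot(all(c("lat", "lon", "beta") %in% names(beta_map)),
            all(c("lat", "lon", "predictor", "value") %in% names(predictors)))
  wide <- tidyr::pivot_wider(predictors, id_cols = c("lat", "lon"),
                             names_from = "predictor",
                             values_from = "value")
  pred_names <- setdiff(names(wide), c("lat", "lon"))
  joined <- dplyr::inner_join(beta_map[, c("lat", "lon", "beta")], wide,
                              by = c("lat", "lon"))
  beta_ok <- is.finite(joined$beta)
  pred_ok <- stats::complete.cases(joined[, pred_names])
  out <- joined[beta_ok & pred_ok, ]
  if (nrow(out) < length(pred_names)) {
    stop("insufficient data: ", nrow(out), " complete cells for ",
         length(pred_names), " predictors", call. = FALSE)
  }
  if (!is.null(crop)) out <- dplyr::mutate(out, crop = crop, .after = "lon")
  attr(out, "n_dropped_beta") <- sum(!beta_ok)
  attr(out, "n_dropped_predictor") <- sum(beta_ok & !pred_ok)
  out
}

#' Attribute the sensitivity pattern to its determinants by random forest
#'
#' Fits a random-forest regression of the per-cell drought sensitivity on
#' the determinant rasters (bootstrap resampling, default hyperparameters,
#' 500 trees) and reports out-of-bag skill: each cell is predicted only by
#' trees whose bootstrap sample excluded it, so `oob_r2 = 1 - SSE_oob /
#' SS_tot` is an internal validation estimate, not a resubstitution fit.
#'
#' @param features Feature table from [build_feature_table()].
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; a fixed seed makes the whole attribution stage
#'   bit-reproducible.
#' @return A `drought_attribution` object: list with `model` (the
#'   randomForest fit), `features`, `predictors`, `oob_r2`, `oob_rmse`,
#'   `n_rows`, `n_trees`, `crop`. Use [glance()] for fit statistics,
#'   [tidy()] or [attribution_importance()] for importances,
#'   [partial_dependence()] for response shapes.
#' @export
fit_attribution <- function(features, n_trees = 500, seed = NULL) {
  pred_names <- setdiff(names(features), c("lat", "lon", "crop", "beta"))
  stopifnot("beta" %in% names(features), length(pred_names) >= 1)
  y <- features$beta
  if (stats::var(y) == 0) {
    stop("degenerate response: sensitivity has zero variance", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- as.data.frame(features[, pred_names])
  model <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  oob <- model$predicted
  sse <- sum((y - oob)^2)
  structure(
    list(model = model,
         features = features,
         predictors = pred_names,
         oob_r2 = 1 - sse / sum((y - mean(y))^2),
         oob_rmse = sqrt(sse / length(y)),
         n_rows = length(y),
         n_trees = n_trees,
         crop = if ("crop" %in% names(features)) features$crop[1] else NA_character_),
    class = "drought_attribution"
  )
}

#' @export
print.drought_attribution <- function(x, ...) {
  cat(sprintf(
    "<drought_attribution> %d cells, %d predictors, %d trees\n  OOB R^2 = %.3f, OOB RMSE = %.3f %%/DI\n",
    x$n_rows, length(x$predictors), x$n_trees, x$oob_r2, x$oob_rmse))
  top <- utils::head(attribution_importance(x), 3)
  cat("  top predictors:", paste(top$predictor, collapse = ", "), "\n")
  invisible(x)
}

#' Variable importance of an attribution fit
#'
#' Impurity (node-variance reduction) importance per predictor, scaled two
#' ways: `share` (importances sum to one) and `normalized` (min-max mapped
#' to \eqn{[0, 1]}, the scale used to compare predictors across crops).
#' Ranks are by descending raw importance, ties broken by column order.
#'
#' @param fit A `drought_attribution` object.
#' @return Tibble `predictor`, `importance`, `share`, `normalized`, `rank`,
#'   ordered by rank.
#' @export
attribution_importance <- function(fit) {
  stopifnot(inherits(fit, "drought_attribution"))
  raw <- randomForest::importance(fit$model)[, "IncNodePurity"]
  raw <- raw[fit$predictors] # stable column order
  rng <- range(raw)
  normalized <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0, length(raw))
  out <- tibble::tibble(
    predictor = fit$predictors,
    importance = unname(raw),
    share = unname(raw) / sum(raw),
    normalized = unname(normalized)
  )
  ord <- order(-out$importance) # ties keep column order (stable)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  dplyr::arrange(out, .data$rank)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname attribution_importance
#' @param x A `drought_attribution` object.
#' @param ... Unused.
#' @method tidy drought_attribution
#' @export
tidy.drought_attribution <- function(x, ...) attribution_importance(x)

#' One-row fit statistics of an attribution fit
#'
#' @param x A `drought_attribution` object.
#' @param ... Unused.
#' @return Tibble `crop`, `oob_r2`, `oob_rmse`, `n_rows`, `n_trees`.
#' @method glance drought_attribution
#' @export
glance.drought_attribution <- function(x, ...) {
  tibble::tibble(crop = x$crop, oob_r2 = x$oob_r2, oob_rmse = x$oob_rmse,
                 n_rows = x$n_rows, n_trees = x$n_trees)
}

#' Partial dependence of sensitivity on a determinant
#'
#' For each evaluation value v (an equally spaced grid between the
#' predictor's 1st and 99th percentile, avoiding extrapolation artifacts in
#' the tails), the partial dependence is the mean model prediction over all
#' training rows with that predictor forced to v and every other column
#' untouched.
#'
#' @param fit A `drought_attribution` object.
#' @param predictors Predictor name(s); default all.
#' @param n_grid Number of evaluation points (default 25).
#' @return Tibble `predictor`, `value`, `estimate`.
#' @export
partial_dependence <- function(fit, predictors = NULL, n_grid = 25) {
  stopifnot(inherits(fit, "drought_attribution"))
  if (is.null(predictors)) predictors <- fit$predictors
  unknown <- setdiff(predictors, fit$predictors)
  if (length(unknown) > 0) {
    stop("unknown predictor: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(fit$features[, fit$predictors])
  purrr::map_dfr(predictors, function(p) {
    qs <- stats::quantile(x[[p]], c(0.01, 0.99), names = FALSE)
    grid <- unique(seq(qs[1], qs[2], length.out = n_grid))
    est <- vapply(grid, function(v) {
      xv <- x
      xv[[p]] <- v
      mean(stats::predict(fit$model, xv))
    }, numeric(1))
    tibble::tibble(predictor = p, value = grid, estimate = est)
  })
}

#' Rank determinants across crops
#'
#' Per-crop top-k determinants by importance rank, plus the overall ranking
#' by mean normalized importance across crops.
#'
#' @param importances Importance tibble with a `crop` column: row-bound
#'   [attribution_importance()] outputs, one per crop.
#' @param k Top-k size (default 6).
#' @return List with `per_crop` (tibble `crop`, `rank`, `predictor`,
#'   `normalized`; rank <= k) and `overall` (tibble `rank`, `predictor`,
#'   `mean_normalized` over all predictors).
#' @export
top_determinants <- function(importances, k = 6) {
  stopifnot(all(c("crop", "predictor", "normalized", "rank") %in%
                  names(importances)))
  per_crop <- importances |>
    dplyr::filter(.data$rank <= k) |>
    dplyr::arrange(.data$crop, .data$rank) |>
    dplyr::select(dplyr::all_of(c("crop", "rank", "predictor", "normalized")))
  overall <- importances |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(mean_normalized = mean(.data$normalized),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_normalized)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  list(per_crop = per_crop, overall = overall)
}
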