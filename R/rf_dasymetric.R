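#' Random-forest hyperparameters
#'
#' Conventional regression-forest defaults: 500 trees, `mtry` one third of
#' the feature count, node size 5, unlimited depth. `min_node_size = Inf`
#' yields a degenerate forest of constant-prediction (root-only) trees —
#' useful as an oracle, since dasymetric redistribution with constant
#' weights reduces exactly to areal weighting.
#'
#' @param trees Number of trees.
#' @param mtry Features tried per split; `NULL` = `floor(n_features / 3)`,
#'   minimum 1.
#' @param min_node_size Minimal node size to attempt a split.
#' @return A `rf_params` list.
#' @export
rf_params <- function(trees = 500, mtry = NULL, min_node_size = 5) {
  structure(list(trees = trees, mtry = mtry, min_node_size = min_node_size),
            class = "rf_params")
}

#' Build the exclusion mask (protected areas plus feature buffers)
#'
#' People are excluded from protected areas and from buffers around the
#' coastline and main roads (default 200 length units, i.e. two cells at
#' 100 m resolution). A cell is buffered when its centre lies within
#' `buffer_distance` of a feature cell centre (exact Euclidean distances).
#'
#' @param protected,roads,coastline Binary [raster_grid()]s, co-registered.
#' @param buffer_distance Buffer radius in length units; default 200.
#' @return Binary [raster_grid()] (1 = excluded).
#' @export
build_exclusion_mask <- function(protected, roads, coastline,
                                 buffer_distance = 200) {
  stopifnot_coregistered(protected, roads, "protected and roads")
  stopifnot_coregistered(protected, coastline, "protected and coastline")
  if (buffer_distance < 0) stop("buffer_distance must be >= 0", call. = FALSE)
  near <- function(mask_grid) {
    if (!any(mask_grid$values == 1)) {
      return(matrix(FALSE, nrow(mask_grid$values), ncol(mask_grid$values)))
    }
    d <- distance_to_class(mask_grid, 1L)
    d$values <= buffer_distance
  }
  m <- (protected$values == 1) | near(roads) | near(coastline)
  raster_grid(matrix(as.integer(m), nrow(m), ncol(m)),
              protected$origin_x, protected$origin_y, protected$cell_size,
              protected$nodata)
}

#' Fit the random-forest density model
#'
#' The response is the log population density of administrative units,
#' `ln(population / unmasked area)`, where area counts only non-excluded
#' cells so the training response and the prediction support agree.
#' Covariates are the zonal aggregates from [zonal_aggregate()]. Zones with
#' zero population or zero unmasked area carry no definable log density and
#' are dropped from training (with a message); at least 10 usable zones are
#' required. The forest keeps its in-bag structure so out-of-bag error and
#' permutation importance can be computed afterwards.
#'
#' @param zonal_table Tibble from [zonal_aggregate()] (columns `zone_id`,
#'   covariates, `n_cells`, `empty`).
#' @param census Census tibble with `zone_id` and `population` for the same
#'   zones.
#' @param areas Tibble from [zone_areas()] (`zone_id`, `area` over unmasked
#'   cells).
#' @param hyperparams An [rf_params()].
#' @param seed Integer seed for the forest.
#' @return A `density_model`: the fitted forest, ordered `feature_names`,
#'   retained training data, OOB predictions and `training_meta`.
#' @export
fit_density_model <- function(zonal_table, census, areas,
                              hyperparams = rf_params(), seed = 1L) {
  feature_names <- setdiff(names(zonal_table),
                           c("zone_id", "n_cells", "empty"))
  if (length(feature_names) == 0) {
    stop("zonal table has no covariate columns", call. = FALSE)
  }
  missing_rows <- setdiff(census$zone_id, zonal_table$zone_id)
  if (length(missing_rows) > 0) {
    stop(sprintf("census zones missing from zonal table: %s",
                 paste(utils::head(missing_rows, 5), collapse = ", ")),
         call. = FALSE)
  }
  d <- dplyr::inner_join(
    dplyr::select(census, "zone_id", "population"),
    dplyr::inner_join(zonal_table,
                      dplyr::select(areas, "zone_id", "area"),
                      by = "zone_id"),
    by = "zone_id"
  )
  usable <- d$population > 0 & d$area > 0 &
    !Reduce(`|`, lapply(d[feature_names], is.na))
  dropped <- d$zone_id[!usable]
  if (length(dropped) > 0) {
    message(sprintf(
      "dropped %d zone(s) with zero population, zero unmasked area or missing covariates: %s",
      length(dropped), paste(utils::head(dropped, 10), collapse = ", ")
    ))
  }
  d <- d[usable, , drop = FALSE]
  if (nrow(d) < 10) {
    stop(sprintf("only %d usable training zones (need >= 10)", nrow(d)),
         call. = FALSE)
  }
  y <- log(d$population / d$area)
  x <- as.data.frame(d[feature_names])
  mtry <- hyperparams$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(length(feature_names) / 3))
  min_node <- hyperparams$min_node_size
  if (is.infinite(min_node)) min_node <- nrow(d) + 1L
  forest <- ranger::ranger(
    x = x, y = y,
    num.trees = hyperparams$trees,
    mtry = mtry,
    min.node.size = min_node,
    keep.inbag = TRUE,
    seed = seed,
    num.threads = 1
  )
  structure(list(
    forest = forest,
    feature_names = feature_names,
    train_x = x,
    train_y = y,
    oob_predictions = forest$predictions,
    dropped_zones = dropped,
    training_meta = list(
      n_units = nrow(d), seed = seed,
      trees = hyperparams$trees, mtry = mtry, min_node_size = min_node,
      oob_mse = mean((forest$predictions - y)^2)
    )
  ), class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  m <- x$training_meta
  cat(sprintf(
    "<density_model> %d trees, mtry %d, %d training zones, OOB MSE %.4g\n",
    m$trees, m$mtry, m$n_units, m$oob_mse
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a fitted density model
#'
#' @param x A `density_model`.
#' @param ... Unused.
#' @return Tibble with `n_units`, `n_features`, `trees`, `mtry`, `oob_mse`,
#'   `oob_r_squared`, `n_dropped`.
#' @export
#' @exportS3Method generics::glance
glance.density_model <- function(x, ...) {
  m <- x$training_meta
  tibble::tibble(
    n_units = m$n_units,
    n_features = length(x$feature_names),
    trees = m$trees,
    mtry = m$mtry,
    oob_mse = m$oob_mse,
    oob_r_squared = 1 - m$oob_mse / stats::var(x$train_y),
    n_dropped = length(x$dropped_zones)
  )
}

#' Per-covariate permutation importance of a density model
#'
#' @param x A `density_model`.
#' @param n_permutations,seed Passed to [covariate_importance()].
#' @param ... Unused.
#' @return The [covariate_importance()] tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.density_model <- function(x, n_permutations = 5, seed = 1L, ...) {
  covariate_importance(x, n_permutations = n_permutations, seed = seed)
}

# per-sample OOB predictions from per-tree predictions + inbag counts
oob_from_trees <- function(tree_preds, inbag) {
  oob <- inbag == 0
  n_oob <- rowSums(oob)
  rowSums(tree_preds * oob) / ifelse(n_oob > 0, n_oob, NA_real_)
}

#' Permutation covariate importance (%IncMSE on out-of-bag error)
#'
#' For each covariate, its training values are randomly permuted and the
#' out-of-bag MSE recomputed from per-tree predictions; importance is
#' `100 * (MSE_oob(permuted) - MSE_oob(original)) / MSE_oob(original)`,
#' averaged over `n_permutations` seeded shuffles. Ranks are 1 = most
#' important, ties breaking by covariate name order.
#'
#' @param model A `density_model` from [fit_density_model()] (retains the
#'   in-bag structure this needs).
#' @param n_permutations Number of permutation replicates (>= 1).
#' @param seed Integer seed for the shuffles.
#' @return Tibble `covariate`, `pct_increase_mse`, `rank`.
#' @export
covariate_importance <- function(model, n_permutations = 5, seed = 1L) {
  stopifnot(inherits(model, "density_model"))
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  x <- model$train_x
  y <- model$train_y
  inbag <- do.call(cbind, model$forest$inbag.counts)
  base_preds <- stats::predict(model$forest, x, predict.all = TRUE,
                               num.threads = 1)$predictions
  mse0 <- mean((oob_from_trees(base_preds, inbag) - y)^2, na.rm = TRUE)
  set.seed(seed)
  inc <- vapply(model$feature_names, function(nm) {
    mean(vapply(seq_len(n_permutations), function(p) {
      xp <- x
      xp[[nm]] <- xp[[nm]][sample.int(nrow(xp))]
      preds <- stats::predict(model$forest, xp, predict.all = TRUE,
                              num.threads = 1)$predictions
      msep <- mean((oob_from_trees(preds, inbag) - y)^2, na.rm = TRUE)
      100 * (msep - mse0) / mse0
    }, numeric(1)))
  }, numeric(1))
  out <- tibble::tibble(
    covariate = model$feature_names,
    pct_increase_mse = unname(inc)
  )
  ord <- order(-out$pct_increase_mse, out$covariate)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  dplyr::arrange(out, .data$rank)
}

#' Predict the pixel-level dasymetric weighting surface
#'
#' Applies the fitted forest to every cell's covariate values and
#' exponentiates the predicted log density; excluded cells get weight 0.
#' Only within-zone weight ratios matter after renormalization, so no
#' back-transform bias correction is applied (any multiplicative correction
#' cancels).
#'
#' @param model A `density_model`.
#' @param stack A `covariate_stack` whose layer names cover the model's
#'   `feature_names`.
#' @param mask Binary [raster_grid()] of excluded cells (1 = excluded).
#' @return A `weight_surface`: list with `weights` ([raster_grid()]) and
#'   `mask`.
#' @export
predict_weight_surface <- function(model, stack, mask) {
  missing <- setdiff(model$feature_names, names(stack$layers))
  extra <- setdiff(names(stack$layers), model$feature_names)
  if (length(missing) > 0) {
    stop(sprintf(
      "stack schema mismatch; missing features: %s%s",
      paste(missing, collapse = ", "),
      if (length(extra) > 0) sprintf(" (extra: %s)", paste(extra, collapse = ", ")) else ""
    ), call. = FALSE)
  }
  ref <- stack$layers[[1]]
  stopifnot_coregistered(ref, mask, "stack and mask")
  keep <- as.vector(mask$values) == 0
  newdata <- as.data.frame(lapply(stack$layers[model$feature_names],
                                  function(g) as.vector(g$values)))
  names(newdata) <- model$feature_names
  w <- numeric(length(keep))
  if (any(keep)) {
    pred <- stats::predict(model$forest, newdata[keep, , drop = FALSE],
                           num.threads = 1)$predictions
    w[keep] <- exp(pred)
  }
  if (!all(is.finite(w))) stop("non-finite weights predicted", call. = FALSE)
  weights <- raster_grid(matrix(w, nrow(ref$values), ncol(ref$values)),
                         ref$origin_x, ref$origin_y, ref$cell_size, ref$nodata)
  structure(list(weights = weights, mask = mask), class = "weight_surface")
}

#' Dasymetrically redistribute census counts over a weighting surface
#'
#' Within each zone, each cell receives
#' `census(zone) * weight(cell) / sum(weights over the zone)`; zonal sums
#' therefore reproduce the census counts exactly (mass conservation). A zone
#' whose weights sum to zero but whose count is positive falls back to
#' uniform allocation over its unmasked cells — or over all its cells if it
#' is fully masked — with a warning.
#'
#' @param weights A `weight_surface` from [predict_weight_surface()] (or a
#'   bare [raster_grid()] of nonnegative weights, taken as unmasked).
#' @param zones An [admin_zones()] co-registered with the weights.
#' @param census Census tibble with `zone_id` and `population` covering all
#'   zones to fill.
#' @return A `population_surface` whose `people_per_cell` sums to the census
#'   count within each zone.
#' @export
dasymetric_redistribute <- function(weights, zones, census) {
  if (inherits(weights, "weight_surface")) {
    w_grid <- weights$weights
    mask_v <- as.vector(weights$mask$values)
  } else {
    w_grid <- weights
    mask_v <- rep(0L, length(w_grid$values))
  }
  stopifnot_coregistered(w_grid, zones$labels, "weights and zones")
  missing <- setdiff(census$zone_id, zones$zones$zone_id)
  if (length(missing) > 0) {
    stop(sprintf("census zones absent from zone set: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  lab <- as.vector(zones$labels$values)
  w <- as.vector(w_grid$values)
  if (any(w < 0)) stop("negative weights", call. = FALSE)
  pop_of <- stats::setNames(census$population, census$zone_id)
  out <- numeric(length(w))
  fallback_zones <- integer(0)
  for (zid in census$zone_id) {
    cells <- which(lab == zid)
    wz <- w[cells]
    sz <- sum(wz)
    p <- pop_of[[as.character(zid)]]
    if (sz > 0) {
      out[cells] <- p * wz / sz
    } else if (p > 0) {
      unm <- cells[mask_v[cells] == 0]
      if (length(unm) == 0) unm <- cells
      out[unm] <- p / length(unm)
      fallback_zones <- c(fallback_zones, zid)
    }
  }
  if (length(fallback_zones) > 0) {
    warning(sprintf(
      "zero-weight zone(s) %s received uniform fallback allocation",
      paste(fallback_zones, collapse = ", ")
    ), call. = FALSE)
  }
  surf <- raster_grid(matrix(out, nrow(w_grid$values), ncol(w_grid$values)),
                      w_grid$origin_x, w_grid$origin_y, w_grid$cell_size,
                      w_grid$nodata)
  structure(list(
    people_per_cell = surf,
    provenance = list(
      source = "dasymetric redistribution",
      level = if ("level" %in% names(census)) census$level[1] else NA_integer_,
      year = if ("year" %in% names(census)) census$year[1] else NA_integer_
    )
  ), class = "population_surface")
}

#' @export
print.population_surface <- function(x, ...) {
  cat(sprintf("<population_surface> total %.2f people on a %d x %d grid\n",
              sum(x$people_per_cell$values), nrow(x$people_per_cell$values),
              ncol(x$people_per_cell$values)))
  invisible(x)
}

#' Areal-weighting baseline surface
#'
#' The naive top-down baseline: each zone's count spread uniformly over its
#' unmasked cells. Equivalent to dasymetric redistribution with constant
#' weights; used as the comparison floor for the forest-weighted method.
#'
#' @param zones An [admin_zones()].
#' @param census Census tibble (`zone_id`, `population`).
#' @param mask Optional binary [raster_grid()] of excluded cells.
#' @return A `population_surface`.
#' @export
areal_weighting <- function(zones, census, mask = NULL) {
  lab <- zones$labels
  if (is.null(mask)) {
    mask <- raster_grid(matrix(0L, nrow(lab$values), ncol(lab$values)),
                        lab$origin_x, lab$origin_y, lab$cell_size, lab$nodata)
  }
  ones <- raster_grid(
    matrix(as.numeric(mask$values == 0), nrow(lab$values), ncol(lab$values)),
    lab$origin_x, lab$origin_y, lab$cell_size, lab$nodata
  )
  ws <- structure(list(weights = ones, mask = mask), class = "weight_surface")
  dasymetric_redistribute(ws, zones, census)
}
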