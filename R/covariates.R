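#' Select the built-up epochs bracketing a target year
#'
#' Settlement layers exist only at a few epochs (the defaults emulate the
#' 1975/1990/2000/2014 satellite epochs); a census year is matched to the
#' nearest epoch at or before it and the nearest at or after it. When the
#' target coincides with an epoch the pair is (target, next epoch) so that
#' linear interpolation reduces to the identity; the final epoch pairs with
#' its predecessor instead.
#'
#' @param target_year Integer year to bracket.
#' @param epochs Sorted integer vector of available epochs (>= 2).
#' @return Integer vector `c(t1, t2)` with `t1 <= target_year <= t2`,
#'   `t1 < t2`.
#' @examples
#' select_bracketing_epochs(1979, c(1975, 1990, 2000, 2014))
#' @export
select_bracketing_epochs <- function(target_year, epochs) {
  epochs <- sort(unique(as.integer(epochs)))
  if (length(epochs) < 2) stop("need at least two epochs", call. = FALSE)
  if (target_year < epochs[1] || target_year > epochs[length(epochs)]) {
    stop(sprintf("target year %d outside epoch span [%d, %d]",
                 target_year, epochs[1], epochs[length(epochs)]),
         call. = FALSE)
  }
  if (target_year == epochs[length(epochs)]) {
    return(c(epochs[length(epochs) - 1L], epochs[length(epochs)]))
  }
  t1 <- max(epochs[epochs <= target_year])
  t2 <- min(epochs[epochs > target_year])
  c(t1, t2)
}

#' Linearly interpolate built-up percentage between two epochs
#'
#' Per cell, `B_t = B_t1 + (t - t1) / (t2 - t1) * (B_t2 - B_t1)`. Linear
#' change between epochs is the weakest assumption available when nothing is
#' known about the timing of settlement growth within the interval. Nodata in
#' either epoch propagates to the output, and results are clamped to
#' \[0, 100\] to guard against input noise (the quantity is a percentage by
#' definition). Extrapolation outside `[t1, t2]` is refused.
#'
#' @param b_t1,b_t2 [raster_grid()]s of built-up percentage at epochs `t1`
#'   and `t2`, co-registered.
#' @param t Target year, `t1 <= t <= t2`.
#' @param t1,t2 Epoch years, `t1 < t2`.
#' @return A [raster_grid()] of built-up percentage at year `t`.
#' @examples
#' b1 <- raster_grid(matrix(10, 1, 1)); b2 <- raster_grid(matrix(40, 1, 1))
#' interpolate_builtup(b1, b2, t = 1979, t1 = 1975, t2 = 1990)$values
#' @export
interpolate_builtup <- function(b_t1, b_t2, t, t1, t2) {
  if (t1 >= t2) stop("need t1 < t2", call. = FALSE)
  if (t < t1 || t > t2) {
    stop(sprintf("t = %g outside [%g, %g]: extrapolation refused", t, t1, t2),
         call. = FALSE)
  }
  stopifnot_coregistered(b_t1, b_t2, "epoch rasters")
  v1 <- values_no_nodata(b_t1)
  v2 <- values_no_nodata(b_t2)
  frac <- (t - t1) / (t2 - t1)
  out <- v1 + frac * (v2 - v1)
  out <- pmin(pmax(out, 0), 100)
  out[is.na(v1) | is.na(v2)] <- b_t1$nodata
  raster_grid(out, b_t1$origin_x, b_t1$origin_y, b_t1$cell_size, b_t1$nodata)
}

#' Euclidean distance to the nearest cell of a class
#'
#' Exact planar Euclidean distance (cell-centre to cell-centre, in length
#' units) from every cell to the nearest cell whose categorical code is in
#' `class_codes`; member cells get 0. If the class is absent from the whole
#' domain the layer is a constant equal to the grid diagonal, with a warning:
#' keeping a fixed layer schema across years is required because the forest
#' needs identical feature sets for training and prediction.
#'
#' @param categorical [raster_grid()] of integer class codes (or a binary
#'   mask; then use `class_codes = 1`).
#' @param class_codes Integer vector of codes counting as members.
#' @return [raster_grid()] of distances.
#' @export
distance_to_class <- function(categorical, class_codes) {
  member <- matrix(categorical$values %in% class_codes,
                   nrow(categorical$values), ncol(categorical$values))
  if (!any(member)) {
    diag_len <- categorical$cell_size *
      sqrt(nrow(member)^2 + ncol(member)^2)
    warning(sprintf(
      "class {%s} absent from domain; returning constant distance %.6g",
      paste(class_codes, collapse = ","), diag_len
    ), call. = FALSE)
    d <- matrix(diag_len, nrow(member), ncol(member))
  } else if (all(member)) {
    d <- matrix(0, nrow(member), ncol(member))
  } else {
    # distmap(x): distance of non-zero pixels to the nearest zero pixel
    d <- as.matrix(EBImage::distmap(1 - member)) * categorical$cell_size
  }
  raster_grid(d, categorical$origin_x, categorical$origin_y,
              categorical$cell_size, categorical$nodata)
}

#' Assemble the covariate stack for one census year
#'
#' The stack carries everything the density model sees for a year:
#' \itemize{
#'   \item `builtup` — built-up percentage linearly interpolated between the
#'     epochs bracketing `year`, then nearest-neighbour resampled to the
#'     reference grid;
#'   \item `lc_class_<k>` / `dist_lc_<k>` — a binary membership layer and a
#'     Euclidean distance-to layer for each non-built land-cover class `k`;
#'   \item `dist_roads`, `dist_rivers` — distances to the road and river
#'     networks;
#'   \item `elevation`, `slope` — time-invariant terrain.
#' }
#' so the layer count is `1 + 2 * length(class_codes) + 4`. Which land-cover
#' map feeds a given year is controlled by `landcover_era_map`, mirroring the
#' practice of holding non-built land cover static over eras where no
#' temporally explicit map exists.
#'
#' @param scene A `synthetic_scene` (or any list with `builtup_by_epoch`,
#'   `landcover`, `elevation`, `slope`, `road_mask`, `river_mask`).
#' @param year Integer census year to build the stack for.
#' @param class_codes Integer vector of non-built land-cover codes to expand
#'   into class/distance layers. Default `1:9`.
#' @param landcover_era_map Optional named list mapping `as.character(year)`
#'   to an element name of `scene$landcover` when `scene$landcover` is a
#'   named list of era maps; ignored when it is a single raster.
#' @param reference Optional [raster_grid()] giving the common grid all
#'   layers are resampled to; defaults to the scene's elevation geometry.
#' @param include_dist_builtup If `TRUE`, adds a `dist_builtup` layer
#'   (distance to any cell with built-up percentage > 0). Off by default:
#'   the percentage layer itself is the settlement predictor.
#' @return A `covariate_stack`: list with `year`, `layers` (named list of
#'   co-registered [raster_grid()]s) and `categorical_names`.
#' @export
build_stack <- function(scene, year, class_codes = 1:9,
                        landcover_era_map = NULL, reference = NULL,
                        include_dist_builtup = FALSE) {
  required <- c("builtup_by_epoch", "landcover", "elevation", "slope",
                "road_mask", "river_mask")
  missing <- setdiff(required, names(scene))
  if (length(missing) > 0) {
    stop(sprintf("scene is missing required layers: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(reference)) reference <- scene$elevation

  epochs <- as.integer(names(scene$builtup_by_epoch))
  br <- select_bracketing_epochs(year, epochs)
  bu <- interpolate_builtup(
    scene$builtup_by_epoch[[as.character(br[1])]],
    scene$builtup_by_epoch[[as.character(br[2])]],
    t = year, t1 = br[1], t2 = br[2]
  )

  lc <- scene$landcover
  if (!inherits(lc, "raster_grid")) {
    key <- if (!is.null(landcover_era_map)) landcover_era_map[[as.character(year)]] else NULL
    if (is.null(key)) {
      stop(sprintf("no land-cover era mapped for year %d", year), call. = FALSE)
    }
    lc <- scene$landcover[[key]]
  }

  on_ref <- function(g) {
    if (is_coregistered(g, reference)) g else resample_nearest(g, reference)
  }
  layers <- list(builtup = on_ref(bu))
  categorical <- character(0)
  lc_ref <- on_ref(lc)
  for (k in class_codes) {
    cls <- raster_grid(
      matrix(as.integer(lc_ref$values == k), nrow(lc_ref$values), ncol(lc_ref$values)),
      lc_ref$origin_x, lc_ref$origin_y, lc_ref$cell_size, lc_ref$nodata
    )
    layers[[sprintf("lc_class_%d", k)]] <- cls
    layers[[sprintf("dist_lc_%d", k)]] <- distance_to_class(lc_ref, k)
    categorical <- c(categorical, sprintf("lc_class_%d", k))
  }
  layers$dist_roads <- on_ref(distance_to_class(scene$road_mask, 1L))
  layers$dist_rivers <- on_ref(distance_to_class(scene$river_mask, 1L))
  layers$elevation <- on_ref(scene$elevation)
  layers$slope <- on_ref(scene$slope)
  if (include_dist_builtup) {
    bu_bin <- layers$builtup
    bu_bin$values <- matrix(as.integer(bu_bin$values > 0),
                            nrow(bu_bin$values), ncol(bu_bin$values))
    layers$dist_builtup <- distance_to_class(bu_bin, 1L)
  }
  structure(
    list(year = as.integer(year), layers = layers,
         categorical_names = categorical),
    class = "covariate_stack"
  )
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> year %d: %d layers (%d categorical)\n",
              x$year, length(x$layers), length(x$categorical_names)))
  invisible(x)
}

#' Aggregate a covariate stack over admin zones
#'
#' Zonal summary feeding the density model: continuous layers are averaged
#' over each zone's non-nodata cells; categorical and binary layers take the
#' majority code, ties breaking toward the smallest code so the result is
#' deterministic and order-independent. Zones with no valid cells yield a
#' flagged row of `NA`s rather than an error.
#'
#' @param stack A `covariate_stack` from [build_stack()].
#' @param zones An [admin_zones()] co-registered with the stack.
#' @return A tibble: one row per zone, columns `zone_id`, one per layer,
#'   `n_cells`, and logical `empty`.
#' @export
zonal_aggregate <- function(stack, zones) {
  ref <- stack$layers[[1]]
  stopifnot_coregistered(ref, zones$labels, "stack and zones")
  lab <- as.vector(zones$labels$values)
  ids <- zones$zones$zone_id
  idx <- match(lab, ids)
  n_cells <- tabulate(idx, nbins = length(ids))

  out <- tibble::tibble(zone_id = ids)
  for (nm in names(stack$layers)) {
    v <- as.vector(values_no_nodata(stack$layers[[nm]]))
    if (nm %in% stack$categorical_names) {
      agg <- vapply(split(v, factor(idx, levels = seq_along(ids))), function(z) {
        z <- z[!is.na(z)]
        if (length(z) == 0) return(NA_real_)
        tab <- table(z)
        # majority; ties toward the smallest code
        as.numeric(names(tab)[which.max(tab)])
      }, numeric(1))
    } else {
      ok <- !is.na(v)
      sums <- rowsum(v[ok], group = factor(idx[ok], levels = seq_along(ids)))[, 1]
      cnts <- tabulate(idx[ok], nbins = length(ids))
      agg <- ifelse(cnts > 0, sums / cnts, NA_real_)
    }
    out[[nm]] <- unname(agg)
  }
  out$n_cells <- n_cells
  out$empty <- n_cells == 0
  if (any(out$empty)) {
    message(sprintf("%d zone(s) have no cells and were flagged", sum(out$empty)))
  }
  out
}
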