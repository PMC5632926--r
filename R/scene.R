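#' Configuration for a synthetic study scene
#'
#' Defines the landscape, admin hierarchy, epochs and census design of a
#' generated scene. Defaults emulate a coastal study area: four settlement
#' epochs bracketing four decadal census years, a shallow three-level admin
#' hierarchy (coarse districts, fine sub-location-like units, finest
#' enumeration-area-like units), density driven chiefly by built-up fraction,
#' and per-district annual growth rates drawn from the 2.76--3.71% range
#' typical of fast-growing coastal districts.
#'
#' @param grid_rows,grid_cols Grid dimensions. Default 100 x 100.
#' @param cell_size Cell side length in abstract metres. Default 100.
#' @param epochs Strictly increasing integer years with built-up layers.
#' @param census_years Integer census years, all within `range(epochs)`.
#' @param n_coarse_zones,n_fine_zones,n_finest_zones Zone counts per level;
#'   must be non-decreasing, and every finer zone nests in exactly one
#'   coarser zone by construction.
#' @param density_coefficients Either a named numeric vector of covariate
#'   effects on log density (applied to every census year), or a named list
#'   `year -> named vector` to express drift in the covariate--density
#'   relationship across years. Covariate names may be `builtup`,
#'   `dist_roads`, `dist_rivers`, `elevation`, `slope`. `NULL` uses a
#'   built-up-dominated default.
#' @param noise_sd SD of Gaussian noise added on the log-density scale.
#' @param rural_baseline Additive density floor (relative to a unit
#'   geometric-mean density) so unsettled rural cells remain populated
#'   rather than empty.
#' @param growth_rates Numeric vector of annual growth rates, one per coarse
#'   zone (recycled); `NULL` draws them from U(0.0276, 0.0371) under the
#'   scene seed.
#' @param exclusion_buffer Buffer (length units) around roads and the
#'   coastline within which, like on protected areas, the true population is
#'   zero. Default 200, matching the modelling exclusion, so the generated
#'   truth respects the support the disaggregation method assumes (people
#'   live only on unmasked cells). Set 0 to zero truth on protected areas
#'   and the bare road/coast cells only.
#' @param base_total Domain population total at the first census year.
#' @param seed Integer seed; identical configs give bit-identical scenes.
#' @return A `scene_config` list.
#' @export
scene_config <- function(grid_rows = 100, grid_cols = 100, cell_size = 100,
                         epochs = c(1975L, 1990L, 2000L, 2014L),
                         census_years = c(1979L, 1989L, 1999L, 2009L),
                         n_coarse_zones = 4, n_fine_zones = 40,
                         n_finest_zones = 160,
                         density_coefficients = NULL,
                         noise_sd = 0.3, rural_baseline = 0.02,
                         growth_rates = NULL, exclusion_buffer = 200,
                         base_total = 1e6, seed = 1L) {
  epochs <- as.integer(epochs)
  census_years <- as.integer(census_years)
  if (any(diff(epochs) <= 0)) {
    stop("epochs must be strictly increasing", call. = FALSE)
  }
  if (any(census_years < min(epochs) | census_years > max(epochs))) {
    stop("census years must lie within the epoch span", call. = FALSE)
  }
  if (!(n_coarse_zones <= n_fine_zones && n_fine_zones <= n_finest_zones)) {
    stop("zone counts must satisfy coarse <= fine <= finest", call. = FALSE)
  }
  if (n_finest_zones > grid_rows * grid_cols) {
    stop("more finest zones than grid cells", call. = FALSE)
  }
  if (is.null(density_coefficients)) {
    density_coefficients <- c(builtup = 1.5, dist_roads = -0.4,
                              dist_rivers = -0.15, elevation = -0.3,
                              slope = -0.1)
  }
  if (!is.list(density_coefficients)) {
    density_coefficients <- stats::setNames(
      rep(list(density_coefficients), length(census_years)),
      as.character(census_years)
    )
  }
  if (!all(as.character(census_years) %in% names(density_coefficients))) {
    stop("density_coefficients list must name every census year", call. = FALSE)
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    cell_size = cell_size, epochs = epochs, census_years = census_years,
    n_coarse_zones = as.integer(n_coarse_zones),
    n_fine_zones = as.integer(n_fine_zones),
    n_finest_zones = as.integer(n_finest_zones),
    density_coefficients = density_coefficients,
    noise_sd = noise_sd, rural_baseline = rural_baseline,
    growth_rates = growth_rates, exclusion_buffer = exclusion_buffer,
    base_total = base_total, seed = as.integer(seed)
  ), class = "scene_config")
}

# separable Gaussian smoothing with reflected edges
smooth_field <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(mm) {
    top <- mm[r:1, , drop = FALSE]
    bot <- mm[nrow(mm):(nrow(mm) - r + 1L), , drop = FALSE]
    padded <- rbind(top, mm, bot)
    f <- stats::filter(padded, k, sides = 2)
    as.matrix(f[(r + 1L):(r + nrow(mm)), , drop = FALSE])
  }
  m1 <- pad_filter(m)
  t(pad_filter(t(m1)))
}

# deterministic relabel of kmeans clusters by centroid order
relabel_clusters <- function(cluster, centers) {
  ord <- order(centers[, 1], centers[, 2])
  match(cluster, ord)
}

# nearest-seed (Voronoi) assignment of cells to seeds; ties -> smallest id
voronoi_assign <- function(nr, nc, seed_rows, seed_cols) {
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  out <- integer(nr * nc)
  chunk <- 8192L
  for (start in seq(1L, nr * nc, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nr * nc)
    d2 <- outer(rows[idx], seed_rows, `-`)^2 + outer(cols[idx], seed_cols, `-`)^2
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  matrix(out, nr, nc)
}

# a random-walk path across the grid; returns a binary matrix
walk_mask <- function(nr, nc, vertical = TRUE) {
  m <- matrix(0L, nr, nc)
  if (vertical) {
    pos <- sample.int(nc, 1)
    for (r in seq_len(nr)) {
      pos <- min(max(pos + sample(-1:1, 1), 1L), nc)
      m[r, pos] <- 1L
    }
  } else {
    pos <- sample.int(nr, 1)
    for (cc in seq_len(nc)) {
      pos <- min(max(pos + sample(-1:1, 1), 1L), nr)
      m[pos, cc] <- 1L
    }
  }
  m
}

disc_mask <- function(nr, nc, centre_row, centre_col, radius) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rows - centre_row)^2 + (cols - centre_col)^2 <= radius^2) * 1L
}

# log1p then z-standardize over all cells (sd 0 -> zeros); covariates with
# negative values (e.g. below-datum elevation) are shifted to start at 0
log_scale <- function(v) {
  mn <- min(v)
  if (mn < 0) v <- v - mn
  z <- log1p(v)
  s <- stats::sd(z)
  if (!is.finite(s) || s == 0) return(z * 0)
  (z - mean(z)) / s
}

#' Generate a seeded synthetic scene with known ground truth
#'
#' Builds a full study environment on a planar grid: nested admin zones by
#' seeded Voronoi growth merged upward with k-means, a smooth terrain field
#' with derived slope, road/river/coastline/protected masks, a categorical
#' land-cover map (9 non-built classes), built-up percentage layers at each
#' epoch growing around seeded urban centres, and a true population surface
#' per census year.
#'
#' Truth construction: per census year, log density is a linear combination
#' of log-scaled covariates (per `density_coefficients`) plus Gaussian noise
#' of sd `noise_sd`; the exponentiated surface gets an additive
#' `rural_baseline` floor, is zeroed on the uninhabitable cells (protected
#' areas plus `exclusion_buffer` around roads and coastline), and is then
#' scaled
#' within each coarse zone so that zone totals follow compound growth at the
#' configured per-zone annual rates from a first-year total of `base_total`
#' (first-year zone shares proportional to the raw density mass). Census
#' tables at every level are exact zonal sums of the truth, so nesting
#' conservation holds by construction.
#'
#' @param config A [scene_config()].
#' @return A `synthetic_scene`: list with `builtup_by_epoch`, `landcover`,
#'   `elevation`, `slope`, `road_mask`, `river_mask`, `protected_mask`,
#'   `coastline_mask`, `zones_by_level` (named list `"1"` coarse .. `"3"`
#'   finest), `truth_by_year`, `census` (tibble over all levels and years),
#'   `meta` (growth rates, base shares, config).
#' @examples
#' sc <- generate_scene(scene_config(grid_rows = 40, grid_cols = 40,
#'   n_coarse_zones = 2, n_fine_zones = 6, n_finest_zones = 12, seed = 7))
#' names(sc$zones_by_level)
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  nr <- config$grid_rows
  nc <- config$grid_cols
  cs <- config$cell_size
  set.seed(config$seed)
  mk <- function(m, nodata = -9999) raster_grid(m, 0, 0, cs, nodata)

  ## admin hierarchy: Voronoi finest zones, k-means merges upward
  seed_idx <- sample.int(nr * nc, config$n_finest_zones)
  seed_rows <- ((seed_idx - 1L) %% nr) + 1L
  seed_cols <- ((seed_idx - 1L) %/% nr) + 1L
  finest_lab <- voronoi_assign(nr, nc, seed_rows, seed_cols)

  coords <- cbind(seed_rows, seed_cols)
  if (config$n_fine_zones == config$n_finest_zones) {
    fine_of_finest <- seq_len(config$n_finest_zones)
  } else {
    km <- stats::kmeans(coords, centers = config$n_fine_zones,
                        nstart = 5, iter.max = 100)
    fine_of_finest <- relabel_clusters(km$cluster, km$centers)
  }
  fine_centers <- apply(coords, 2, function(v) tapply(v, fine_of_finest, mean))
  fine_centers <- matrix(fine_centers, ncol = 2)
  if (config$n_coarse_zones == config$n_fine_zones) {
    coarse_of_fine <- seq_len(config$n_fine_zones)
  } else {
    km2 <- stats::kmeans(fine_centers, centers = config$n_coarse_zones,
                         nstart = 5, iter.max = 100)
    coarse_of_fine <- relabel_clusters(km2$cluster, km2$centers)
  }

  finest_tab <- tibble::tibble(
    zone_id = seq_len(config$n_finest_zones),
    parent_id = as.integer(fine_of_finest),
    level = 3L
  )
  fine_tab <- tibble::tibble(
    zone_id = seq_len(config$n_fine_zones),
    parent_id = as.integer(coarse_of_fine),
    level = 2L
  )
  coarse_tab <- tibble::tibble(
    zone_id = seq_len(config$n_coarse_zones),
    parent_id = NA_integer_,
    level = 1L
  )
  zones3 <- admin_zones(mk(finest_lab), finest_tab)
  zones2 <- coarsen_zones(zones3, fine_tab)
  zones1 <- coarsen_zones(zones2, coarse_tab)
  zones_by_level <- list(`1` = zones1, `2` = zones2, `3` = zones3)

  ## terrain
  elev_raw <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                           sigma = max(2, nr / 12))
  elev <- 200 + 80 * (elev_raw - mean(elev_raw)) / stats::sd(elev_raw)
  dzdx <- cbind(elev[, 2] - elev[, 1],
                (elev[, -(1:2), drop = FALSE] - elev[, 1:(nc - 2), drop = FALSE]) / 2,
                elev[, nc] - elev[, nc - 1]) / cs
  dzdy <- rbind(elev[2, ] - elev[1, ],
                (elev[-(1:2), , drop = FALSE] - elev[1:(nr - 2), , drop = FALSE]) / 2,
                elev[nr, ] - elev[nr - 1, ]) / cs
  slope <- sqrt(dzdx^2 + dzdy^2) * 100  # percent rise over run

  ## linear features and protected areas
  river_mask <- walk_mask(nr, nc, vertical = TRUE) | walk_mask(nr, nc, vertical = TRUE)
  river_mask <- matrix(as.integer(river_mask), nr, nc)
  road_mask <- walk_mask(nr, nc, vertical = FALSE)
  coast_col <- nc - max(2L, round(nc * 0.04))
  road_v <- matrix(0L, nr, nc)
  road_v[, coast_col] <- 1L
  road_mask <- matrix(as.integer(road_mask | road_v), nr, nc)
  coastline_mask <- matrix(0L, nr, nc)
  coastline_mask[, nc] <- 1L
  protected_mask <- matrix(0L, nr, nc)
  for (i in 1:3) {
    protected_mask <- protected_mask |
      disc_mask(nr, nc, sample.int(nr, 1), sample.int(nc, 1),
                max(3, round(min(nr, nc) / 14)))
  }
  protected_mask <- matrix(as.integer(protected_mask), nr, nc)

  ## land cover: 7 quantile classes of a smooth field, water on rivers,
  ## a small cloud/nodata patch (class 9)
  lc_field <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                           sigma = max(2, nr / 20))
  qs <- stats::quantile(lc_field, probs = seq(0, 1, length.out = 8))
  landcover <- matrix(as.integer(cut(lc_field, breaks = unique(qs),
                                     include.lowest = TRUE)), nr, nc)
  landcover[river_mask == 1] <- 8L
  cloud <- disc_mask(nr, nc, sample.int(nr, 1), sample.int(nc, 1),
                     max(2, round(min(nr, nc) / 25)))
  landcover[cloud == 1] <- 9L

  ## built-up epochs: settlement cores grow in extent and intensity
  n_centres <- 3L
  ctr_rows <- sample.int(nr, n_centres)
  ctr_cols <- c(sample(seq(round(0.7 * nc), max(round(0.7 * nc) + 1, coast_col)), 1),
                sample.int(nc, n_centres - 1L))
  amps <- c(1, 0.45, 0.3)
  rows_m <- matrix(seq_len(nr), nr, nc)
  cols_m <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  bu_noise <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                           sigma = max(1.5, nr / 30))
  builtup_by_epoch <- list()
  for (i in seq_along(config$epochs)) {
    r_i <- max(2, min(nr, nc) / 18) * (1 + 0.35 * (i - 1))
    a_i <- 55 * (1 + 0.4 * (i - 1))
    b <- matrix(0, nr, nc)
    for (j in seq_len(n_centres)) {
      d <- sqrt((rows_m - ctr_rows[j])^2 + (cols_m - ctr_cols[j])^2)
      b <- b + a_i * amps[j] * exp(-d / r_i)
    }
    b <- b * exp(0.25 * bu_noise)
    b[b < 0.5] <- 0  # no sub-half-percent scatter far from settlements
    b <- pmin(pmax(b, 0), 100)
    b[protected_mask == 1] <- 0
    builtup_by_epoch[[as.character(config$epochs[i])]] <- mk(b)
  }

  scene_layers <- list(
    builtup_by_epoch = builtup_by_epoch,
    landcover = mk(landcover),
    elevation = mk(elev),
    slope = mk(slope),
    road_mask = mk(road_mask),
    river_mask = mk(river_mask),
    protected_mask = mk(protected_mask),
    coastline_mask = mk(coastline_mask)
  )

  ## covariate values feeding the truth surface
  dist_roads <- distance_to_class(scene_layers$road_mask, 1L)$values
  dist_rivers <- distance_to_class(scene_layers$river_mask, 1L)$values
  cov_fun <- function(name, year) {
    switch(name,
      builtup = {
        br <- select_bracketing_epochs(year, config$epochs)
        interpolate_builtup(builtup_by_epoch[[as.character(br[1])]],
                            builtup_by_epoch[[as.character(br[2])]],
                            t = year, t1 = br[1], t2 = br[2])$values
      },
      dist_roads = dist_roads,
      dist_rivers = dist_rivers,
      elevation = elev,
      slope = slope,
      stop(sprintf("unknown truth covariate '%s'", name), call. = FALSE)
    )
  }

  ## uninhabitable cells: protected areas plus road/coast buffers, so the
  ## truth lives on the same support the disaggregation method assumes
  excl <- build_exclusion_mask(scene_layers$protected_mask,
                               scene_layers$road_mask,
                               scene_layers$coastline_mask,
                               buffer_distance = config$exclusion_buffer)

  ## per-coarse-zone growth
  growth <- config$growth_rates
  if (is.null(growth)) {
    growth <- stats::runif(config$n_coarse_zones, 0.0276, 0.0371)
  }
  growth <- rep_len(growth, config$n_coarse_zones)

  years <- config$census_years
  y0 <- years[1]
  coarse_lab <- as.vector(zones1$labels$values)
  raw_by_year <- list()
  for (y in years) {
    coefs <- config$density_coefficients[[as.character(y)]]
    lin <- matrix(0, nr, nc)
    for (nm in names(coefs)) {
      if (coefs[[nm]] == 0) next
      lin <- lin + coefs[[nm]] * matrix(log_scale(as.vector(cov_fun(nm, y))), nr, nc)
    }
    eps <- if (config$noise_sd > 0) {
      matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    } else {
      matrix(0, nr, nc)
    }
    raw <- exp(lin + eps) + config$rural_baseline
    raw[excl$values == 1] <- 0
    raw_by_year[[as.character(y)]] <- raw
  }

  raw0_sums <- as.vector(rowsum(as.vector(raw_by_year[[as.character(y0)]]),
                                group = coarse_lab))
  base_shares <- raw0_sums / sum(raw0_sums)
  truth_by_year <- list()
  for (y in years) {
    raw <- raw_by_year[[as.character(y)]]
    raw_sums <- as.vector(rowsum(as.vector(raw), group = coarse_lab))
    targets <- base_shares * config$base_total * (1 + growth)^(y - y0)
    scale_z <- ifelse(raw_sums > 0, targets / raw_sums, 0)
    truth <- raw * matrix(scale_z[coarse_lab], nr, nc)
    truth_by_year[[as.character(y)]] <- structure(
      list(people_per_cell = mk(truth),
           provenance = list(source = "synthetic truth", year = y)),
      class = "population_surface"
    )
  }

  ## census tables at every level and year (exact zonal sums of truth)
  census <- dplyr::bind_rows(lapply(years, function(y) {
    dplyr::bind_rows(lapply(names(zones_by_level), function(lv) {
      aggregate_truth(truth_by_year[[as.character(y)]],
                      zones_by_level[[lv]], year = y)
    }))
  }))

  structure(c(scene_layers, list(
    zones_by_level = zones_by_level,
    truth_by_year = truth_by_year,
    census = census,
    meta = list(growth_rates = growth, base_shares = base_shares,
                exclusion_mask = excl, config = config)
  )), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cfg <- x$meta$config
  cat(sprintf(
    "<synthetic_scene> %d x %d grid, %d/%d/%d zones, epochs %s, census years %s\n",
    cfg$grid_rows, cfg$grid_cols, cfg$n_coarse_zones, cfg$n_fine_zones,
    cfg$n_finest_zones, paste(cfg$epochs, collapse = "/"),
    paste(cfg$census_years, collapse = "/")
  ))
  invisible(x)
}

#' Aggregate a population surface into a census table
#'
#' Sums a gridded population surface within each admin zone — the same
#' summation used both to build ground-truth census tables and to validate
#' predictions by reaggregation. Conservation: the counts sum to the domain
#' total of the surface.
#'
#' @param truth A `population_surface` (or bare [raster_grid()] of people
#'   per cell).
#' @param zones An [admin_zones()] co-registered with the surface.
#' @param year Optional census year recorded in the output.
#' @return A tibble `zone_id`, `level`, `year`, `population`, `area`,
#'   `n_cells`.
#' @export
aggregate_truth <- function(truth, zones, year = NA_integer_) {
  grid <- if (inherits(truth, "population_surface")) truth$people_per_cell else truth
  stopifnot_coregistered(grid, zones$labels, "surface and zones")
  lab <- as.vector(zones$labels$values)
  ids <- zones$zones$zone_id
  idx <- match(lab, ids)
  n_cells <- tabulate(idx, nbins = length(ids))
  if (any(n_cells == 0)) {
    stop(sprintf("zone(s) with no cells: %s",
                 paste(ids[n_cells == 0], collapse = ", ")), call. = FALSE)
  }
  pop <- as.vector(rowsum(as.vector(grid$values),
                          group = factor(idx, levels = seq_along(ids))))
  tibble::tibble(
    zone_id = ids,
    level = zones$zones$level,
    year = as.integer(year),
    population = pop,
    area = n_cells * grid$cell_size^2,
    n_cells = n_cells
  )
}

#' Extract one census table from a scene
#'
#' @param scene A `synthetic_scene`.
#' @param level Admin level (1 = coarsest).
#' @param year Census year.
#' @return Tibble of that level/year's census records.
#' @export
get_census <- function(scene, level, year) {
  out <- dplyr::filter(scene$census, .data$level == !!level, .data$year == !!year)
  if (nrow(out) == 0) {
    stop(sprintf("no census table at level %d, year %d", level, year),
         call. = FALSE)
  }
  out
}

#' Round census counts preserving totals (largest remainder)
#'
#' Optional integerization for realism: floors every count and hands the
#' remaining units to the zones with the largest fractional parts, so the
#' table total changes by less than 1 person and conservation checks against
#' the rounded total remain exact.
#'
#' @param census Census tibble with a `population` column.
#' @return Same tibble with integer `population`.
#' @export
integerize_counts <- function(census) {
  p <- census$population
  total <- round(sum(p))
  fl <- floor(p)
  rem <- total - sum(fl)
  if (rem > 0) {
    give <- order(p - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  census$population <- as.integer(fl)
  census
}

#' Write and read a scene directory
#'
#' Serializes every raster as an Esri ASCII grid, zones as label raster +
#' CSV pairs, the census as CSV (`zone_id,level,year,population,area`), and
#' the configuration as YAML. Truth surfaces are written as
#' `truth_<year>.asc`.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Directory to write into (created if needed).
#' @return `write_scene()` returns `dir` invisibly; `read_scene()` a
#'   `synthetic_scene`.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ep in names(scene$builtup_by_epoch)) {
    write_raster(scene$builtup_by_epoch[[ep]],
                 file.path(dir, sprintf("builtup_%s.asc", ep)))
  }
  for (nm in c("landcover", "elevation", "slope", "road_mask", "river_mask",
               "protected_mask", "coastline_mask")) {
    write_raster(scene[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  for (lv in names(scene$zones_by_level)) {
    write_zones(scene$zones_by_level[[lv]],
                file.path(dir, sprintf("zones_level%s", lv)))
  }
  for (y in names(scene$truth_by_year)) {
    write_raster(scene$truth_by_year[[y]]$people_per_cell,
                 file.path(dir, sprintf("truth_%s.asc", y)))
  }
  utils::write.csv(scene$census[, c("zone_id", "level", "year", "population", "area")],
                   file.path(dir, "census.csv"), row.names = FALSE)
  cfg <- scene$meta$config
  cfg_list <- unclass(cfg)
  cfg_list$density_coefficients <- lapply(cfg_list$density_coefficients, as.list)
  yaml::write_yaml(cfg_list, file.path(dir, "scene_config.yaml"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  bu_files <- list.files(dir, pattern = "^builtup_\\d+\\.asc$")
  epochs <- sort(as.integer(gsub("\\D", "", bu_files)))
  builtup_by_epoch <- stats::setNames(
    lapply(epochs, function(e) read_raster(file.path(dir, sprintf("builtup_%d.asc", e)))),
    as.character(epochs)
  )
  layers <- lapply(
    stats::setNames(nm = c("landcover", "elevation", "slope", "road_mask",
                           "river_mask", "protected_mask", "coastline_mask")),
    function(nm) read_raster(file.path(dir, paste0(nm, ".asc")))
  )
  lv_files <- list.files(dir, pattern = "^zones_level\\d+\\.csv$")
  levels <- sort(gsub("\\D", "", lv_files))
  zones_by_level <- stats::setNames(
    lapply(levels, function(lv) read_zones(file.path(dir, sprintf("zones_level%s", lv)))),
    levels
  )
  census <- tibble::as_tibble(utils::read.csv(file.path(dir, "census.csv")))
  truth_files <- list.files(dir, pattern = "^truth_\\d+\\.asc$")
  years <- sort(as.integer(gsub("\\D", "", truth_files)))
  truth_by_year <- stats::setNames(lapply(years, function(y) {
    structure(list(
      people_per_cell = read_raster(file.path(dir, sprintf("truth_%d.asc", y))),
      provenance = list(source = "synthetic truth", year = y)
    ), class = "population_surface")
  }), as.character(years))
  cfgl <- yaml::read_yaml(file.path(dir, "scene_config.yaml"))
  cfg <- scene_config(
    grid_rows = cfgl$grid_rows, grid_cols = cfgl$grid_cols,
    cell_size = cfgl$cell_size, epochs = unlist(cfgl$epochs),
    census_years = unlist(cfgl$census_years),
    n_coarse_zones = cfgl$n_coarse_zones, n_fine_zones = cfgl$n_fine_zones,
    n_finest_zones = cfgl$n_finest_zones,
    density_coefficients = lapply(cfgl$density_coefficients, unlist),
    noise_sd = cfgl$noise_sd, rural_baseline = cfgl$rural_baseline,
    growth_rates = unlist(cfgl$growth_rates),
    exclusion_buffer = cfgl$exclusion_buffer %||% 200,
    base_total = cfgl$base_total, seed = cfgl$seed
  )
  structure(c(list(builtup_by_epoch = builtup_by_epoch), layers, list(
    zones_by_level = zones_by_level,
    truth_by_year = truth_by_year,
    census = census,
    meta = list(growth_rates = unlist(cfgl$growth_rates), config = cfg)
  )), class = "synthetic_scene")
}
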