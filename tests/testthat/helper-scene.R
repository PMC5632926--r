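# shared fixtures: scenes are generated once per run and memoized by key

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, config) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, generate_scene(config), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

# the workhorse scene: 60x60 grid, 4 coarse / 20 fine / 60 finest zones,
# four census years, default built-up-dominated density
default_scene <- function() {
  cached_scene("default", scene_config(
    grid_rows = 60, grid_cols = 60,
    n_coarse_zones = 4, n_fine_zones = 20, n_finest_zones = 60,
    seed = 42
  ))
}

default_mask <- function() {
  sc <- default_scene()
  build_exclusion_mask(sc$protected_mask, sc$road_mask, sc$coastline_mask, 200)
}

# stack + zonal table + areas + model for the default scene, year 1979
default_fit <- function() {
  if (!exists("fit1979", envir = .scene_cache)) {
    sc <- default_scene()
    mask <- default_mask()
    st <- build_stack(sc, 1979)
    zones3 <- sc$zones_by_level[["3"]]
    zt <- zonal_aggregate(st, zones3)
    ar <- zone_areas(zones3, mask)
    model <- suppressMessages(fit_density_model(
      zt, get_census(sc, 3, 1979), ar,
      hyperparams = rf_params(trees = 300), seed = 3
    ))
    assign("fit1979", list(scene = sc, mask = mask, stack = st,
                           zones3 = zones3, zonal = zt, areas = ar,
                           model = model), envir = .scene_cache)
  }
  get("fit1979", envir = .scene_cache)
}

# tiny manual geometry helpers
grid_of <- function(values, cell_size = 1, byrow = TRUE) {
  raster_grid(matrix(values, nrow = sqrt(length(values)), byrow = byrow),
              cell_size = cell_size)
}

# a 2x2 grid split into left/right column zones
two_col_zones <- function(cell_size = 1) {
  lab <- raster_grid(matrix(c(1L, 1L, 2L, 2L), 2, 2), cell_size = cell_size)
  admin_zones(lab, tibble::tibble(zone_id = 1:2, parent_id = NA_integer_,
                                  level = 1L))
}
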