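test_that("exclusion mask is the union of protected areas and feature buffers", {
  zero <- raster_grid(matrix(0L, 9, 9), cell_size = 100)
  m0 <- build_exclusion_mask(zero, zero, zero, 200)
  expect_true(all(m0$values == 0))

  # single road cell with a 200 m buffer at 100 m cells: Euclidean disc r = 2
  road <- raster_grid(matrix(0L, 9, 9), cell_size = 100)
  road$values[5, 5] <- 1L
  m <- build_exclusion_mask(zero, road, zero, 200)
  rows <- matrix(1:9, 9, 9); cols <- t(rows)
  in_disc <- (rows - 5)^2 + (cols - 5)^2 <= 4
  expect_identical(m$values == 1, in_disc)

  # a protected cell outside any buffer is still masked
  prot <- raster_grid(matrix(0L, 9, 9), cell_size = 100)
  prot$values[1, 9] <- 1L
  m2 <- build_exclusion_mask(prot, road, zero, 200)
  expect_equal(m2$values[1, 9], 1L)
})

test_that("constant log density is recovered out-of-bag", {
  f <- default_fit()
  const_census <- tibble::tibble(zone_id = f$areas$zone_id,
                                 population = exp(2) * f$areas$area)
  m <- suppressMessages(fit_density_model(f$zonal, const_census, f$areas,
                         hyperparams = rf_params(trees = 200), seed = 3))
  expect_lt(stats::sd(m$oob_predictions), 0.05)
  expect_equal(mean(m$oob_predictions), 2, tolerance = 1e-6)
})

test_that("training drops degenerate zones and enforces the minimum count", {
  f <- default_fit()
  census <- get_census(f$scene, 3, 1979)
  # zero out one zone's population: it must be dropped with a message
  census$population[census$zone_id == 5] <- 0
  expect_message(
    m <- fit_density_model(f$zonal, census, f$areas,
                           hyperparams = rf_params(trees = 50), seed = 1),
    "dropped"
  )
  expect_true(5 %in% m$dropped_zones)
  # fewer than 10 usable zones errors
  tiny <- census[1:6, ]
  expect_error(
    suppressMessages(fit_density_model(f$zonal[f$zonal$zone_id %in% tiny$zone_id, ],
                                       tiny, f$areas,
                                       hyperparams = rf_params(trees = 50))),
    "usable training zones"
  )
})

test_that("a duplicated covariate shares the original's importance", {
  f <- default_fit()
  census <- get_census(f$scene, 3, 1979)
  zt2 <- f$zonal
  zt2$builtup_twin <- zt2$builtup
  m_twin <- suppressMessages(fit_density_model(
    zt2, census, f$areas, hyperparams = rf_params(trees = 300), seed = 3
  ))
  i_single <- covariate_importance(f$model, n_permutations = 3, seed = 1)
  i_twin <- covariate_importance(m_twin, n_permutations = 3, seed = 1)
  single <- i_single$pct_increase_mse[i_single$covariate == "builtup"]
  twins <- i_twin$pct_increase_mse[i_twin$covariate %in%
                                     c("builtup", "builtup_twin")]
  expect_length(twins, 2)
  expect_true(all(twins > 0))
  # the pair's summed importance is comparable to the single column's
  expect_gt(sum(twins), 0.5 * single)
  expect_lt(sum(twins), 3 * single)
})

test_that("weight surfaces honour the mask, schema and determinism", {
  f <- default_fit()
  # fully masked domain -> all-zero weights
  all_mask <- raster_grid(matrix(1L, 60, 60), cell_size = 100)
  ws0 <- predict_weight_surface(f$model, f$stack, all_mask)
  expect_true(all(ws0$weights$values == 0))
  # schema mismatch names the missing feature
  st_broken <- f$stack
  st_broken$layers$builtup <- NULL
  expect_error(predict_weight_surface(f$model, st_broken, f$mask), "builtup")
  # weights are a deterministic function of covariates: cells with equal
  # covariate vectors get equal weights
  ws <- predict_weight_surface(f$model, f$stack, f$mask)
  expect_true(all(is.finite(ws$weights$values)))
  expect_true(all(ws$weights$values >= 0))
  expect_true(all(ws$weights$values[f$mask$values == 1] == 0))
  ws_again <- predict_weight_surface(f$model, f$stack, f$mask)
  expect_identical(ws$weights$values, ws_again$weights$values)
})

test_that("predicted weights track built-up fraction on a strong-signal scene", {
  sc <- cached_scene("strong", scene_config(
    grid_rows = 60, grid_cols = 60, n_coarse_zones = 4, n_fine_zones = 16,
    n_finest_zones = 120, seed = 21, noise_sd = 0.1,
    density_coefficients = c(builtup = 2), census_years = 1979L
  ))
  mask <- build_exclusion_mask(sc$protected_mask, sc$road_mask,
                               sc$coastline_mask, 200)
  st <- build_stack(sc, 1979)
  zones3 <- sc$zones_by_level[["3"]]
  model <- suppressMessages(fit_density_model(
    zonal_aggregate(st, zones3), get_census(sc, 3, 1979),
    zone_areas(zones3, mask), hyperparams = rf_params(trees = 300), seed = 2
  ))
  ws <- predict_weight_surface(model, st, mask)
  unm <- mask$values == 0
  rho <- stats::cor(ws$weights$values[unm], st$layers$builtup$values[unm],
                    method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("redistribution splits counts proportionally with exact conservation", {
  # 3-cell zone with weights (1,2,3) and count 60 -> (10, 20, 30)
  lab <- raster_grid(matrix(c(1L, 1L, 1L, 2L), 2, 2), cell_size = 1)
  zones <- admin_zones(lab, tibble::tibble(zone_id = 1:2,
                                           parent_id = NA_integer_,
                                           level = 1L))
  w <- raster_grid(matrix(c(1, 2, 3, 1), 2, 2), cell_size = 1)
  census <- tibble::tibble(zone_id = 1:2, population = c(60, 5))
  out <- dasymetric_redistribute(w, zones, census)
  expect_equal(out$people_per_cell$values[, 1], c(10, 20))
  expect_equal(out$people_per_cell$values[1, 2], 30)
  expect_equal(out$people_per_cell$values[2, 2], 5)

  # uniform weights -> equal shares
  wu <- raster_grid(matrix(1, 2, 2), cell_size = 1)
  outu <- dasymetric_redistribute(wu, zones, census)
  expect_equal(as.vector(outu$people_per_cell$values)[1:3], rep(20, 3))

  # zone in census but absent from zones errors
  bad_census <- tibble::tibble(zone_id = c(1, 9), population = c(1, 1))
  expect_error(dasymetric_redistribute(w, zones, bad_census), "9")
})

test_that("zero-weight zones fall back to uniform allocation with a warning", {
  lab <- raster_grid(matrix(1L, 1, 5), cell_size = 1)
  zones <- admin_zones(lab, tibble::tibble(zone_id = 1L,
                                           parent_id = NA_integer_,
                                           level = 1L))
  w <- raster_grid(matrix(0, 1, 5), cell_size = 1)
  mask <- raster_grid(matrix(0L, 1, 5), cell_size = 1)
  ws <- structure(list(weights = w, mask = mask), class = "weight_surface")
  census <- tibble::tibble(zone_id = 1L, population = 50)
  expect_warning(out <- dasymetric_redistribute(ws, zones, census),
                 "fallback")
  expect_equal(as.vector(out$people_per_cell$values), rep(10, 5))
})

test_that("redistribution is scale-equivariant in the census counts", {
  f <- default_fit()
  ws <- predict_weight_surface(f$model, f$stack, f$mask)
  census <- get_census(f$scene, 1, 1979)
  out1 <- dasymetric_redistribute(ws, f$scene$zones_by_level[["1"]], census)
  census4 <- dplyr::mutate(census, population = population * 4)
  out4 <- dasymetric_redistribute(ws, f$scene$zones_by_level[["1"]], census4)
  expect_identical(out4$people_per_cell$values, 4 * out1$people_per_cell$values)
})

test_that("a constant-prediction forest reduces redistribution to areal weighting", {
  f <- default_fit()
  census <- get_census(f$scene, 1, 1979)
  m_const <- suppressMessages(fit_density_model(
    f$zonal, get_census(f$scene, 3, 1979), f$areas,
    hyperparams = rf_params(trees = 50, min_node_size = Inf), seed = 2
  ))
  ws <- predict_weight_surface(m_const, f$stack, f$mask)
  out <- dasymetric_redistribute(ws, f$scene$zones_by_level[["1"]], census)
  base <- areal_weighting(f$scene$zones_by_level[["1"]], census, f$mask)
  expect_equal(out$people_per_cell$values, base$people_per_cell$values,
               tolerance = 1e-12)
})

test_that("mass conservation holds for forest-weighted redistribution", {
  f <- default_fit()
  ws <- predict_weight_surface(f$model, f$stack, f$mask)
  census <- get_census(f$scene, 1, 1979)
  out <- dasymetric_redistribute(ws, f$scene$zones_by_level[["1"]], census)
  sums <- aggregate_truth(out, f$scene$zones_by_level[["1"]])
  expect_equal(sums$population, census$population, tolerance = 1e-9)
  expect_equal(sum(out$people_per_cell$values), sum(census$population),
               tolerance = 1e-9)
  expect_true(all(out$people_per_cell$values >= 0))
  expect_true(all(out$people_per_cell$values[f$mask$values == 1] == 0))
})

test_that("permutation importance behaves at its degenerate and noise limits", {
  f <- default_fit()
  census <- get_census(f$scene, 3, 1979)
  expect_error(covariate_importance(f$model, n_permutations = 0),
               "n_permutations")
  # constant covariate: importance ~ 0
  zt_const <- f$zonal
  zt_const$flat <- 1
  m_const <- suppressMessages(fit_density_model(
    zt_const, census, f$areas, hyperparams = rf_params(trees = 200), seed = 3
  ))
  i_const <- covariate_importance(m_const, n_permutations = 3, seed = 1)
  expect_lt(abs(i_const$pct_increase_mse[i_const$covariate == "flat"]), 1)
  # pure-noise covariate: near zero and below the informative covariates
  zt_noise <- f$zonal
  set.seed(9)
  zt_noise$noise_cov <- stats::rnorm(nrow(zt_noise))
  m_noise <- suppressMessages(fit_density_model(
    zt_noise, census, f$areas, hyperparams = rf_params(trees = 300), seed = 3
  ))
  i_noise <- covariate_importance(m_noise, n_permutations = 3, seed = 1)
  noise_imp <- i_noise$pct_increase_mse[i_noise$covariate == "noise_cov"]
  expect_lt(abs(noise_imp), 10)
  for (nm in c("builtup", "dist_roads", "elevation")) {
    expect_lt(noise_imp, i_noise$pct_increase_mse[i_noise$covariate == nm])
  }
  # built-up ranks first on a settlement-driven scene
  i_main <- covariate_importance(f$model, n_permutations = 3, seed = 1)
  expect_equal(i_main$covariate[i_main$rank == 1], "builtup")
  expect_equal(sort(i_main$rank), seq_len(nrow(i_main)))
})

test_that("importance agrees with an independent forest implementation on the dominant covariate", {
  f <- default_fit()
  imp <- covariate_importance(f$model, n_permutations = 3, seed = 1)
  set.seed(1)
  rf <- randomForest::randomForest(x = f$model$train_x, y = f$model$train_y,
                                   ntree = 300, importance = TRUE)
  ri <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  # both routes rank built-up first and far above the bulk of covariates
  expect_equal(imp$covariate[imp$rank == 1], "builtup")
  expect_equal(names(which.max(ri)), "builtup")
  expect_gt(imp$pct_increase_mse[imp$covariate == "builtup"],
            10 * stats::median(imp$pct_increase_mse))
  expect_gt(ri[["builtup"]], 10 * stats::median(ri))
})
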