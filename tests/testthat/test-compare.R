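test_that("reaggregation metrics reproduce closed-form values", {
  # two zones of one cell each; craft surfaces with known residuals
  lab <- raster_grid(matrix(c(1L, 2L), 1, 2), cell_size = 1)
  zones <- admin_zones(lab, tibble::tibble(zone_id = 1:2,
                                           parent_id = NA_integer_,
                                           level = 1L))
  census <- tibble::tibble(zone_id = 1:2, population = c(100, 100))
  surf <- function(vals) {
    structure(list(people_per_cell = raster_grid(matrix(vals, 1, 2),
                                                 cell_size = 1),
                   provenance = list()), class = "population_surface")
  }
  # residuals (+10, -10): mae = rmse = 10
  v1 <- validate_by_reaggregation(surf(c(110, 90)), zones, census)
  expect_equal(v1$mae, 10)
  expect_equal(v1$rmse, 10)
  # residuals (0, 30): mae = 15, rmse = sqrt(450)
  v2 <- validate_by_reaggregation(surf(c(100, 130)), zones, census)
  expect_equal(v2$mae, 15)
  expect_equal(v2$rmse, sqrt(450))
  expect_equal(v2$rmse, 21.2132, tolerance = 1e-4)
  expect_equal(v2$n_units, 2)
  # census zone missing from the zone set errors
  bad <- tibble::tibble(zone_id = c(1, 3), population = c(1, 1))
  expect_error(validate_by_reaggregation(surf(c(1, 1)), zones, bad), "3")
})

test_that("redistributing at the evaluation level itself scores zero error", {
  f <- default_fit()
  zones2 <- f$scene$zones_by_level[["2"]]
  census2 <- get_census(f$scene, 2, 1979)
  ws <- predict_weight_surface(f$model, f$stack, f$mask)
  surf <- dasymetric_redistribute(ws, zones2, census2)
  v <- validate_by_reaggregation(surf, zones2, census2)
  expect_equal(v$rmse, 0, tolerance = 1e-9)
  expect_equal(v$mae, 0, tolerance = 1e-9)
})

test_that("RMSE >= MAE with equality only for equal-magnitude residuals", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    res <- stats::rnorm(n, sd = sample(c(0.1, 10, 1000), 1))
    rmse <- sqrt(mean(res^2))
    mae <- mean(abs(res))
    expect_gte(rmse + 1e-12, mae)
  }
  # equality case
  res <- c(3, -3, 3)
  expect_equal(sqrt(mean(res^2)), mean(abs(res)))
})

test_that("validation residuals cancel within each redistribution zone", {
  f <- default_fit()
  sc <- f$scene
  spec <- scheme_spec("M1", years = 1979L, training_year = 1979L,
                      training_level = 3L, evaluation_level = 2L,
                      redistribution_level = 1L)
  m1 <- run_m1(sc, spec, hyperparams = rf_params(trees = 100), seed = 1)
  rep <- validate_schemes(list(M1 = m1), sc, evaluation_level = 2L)
  res <- rep$residuals[[1]]
  parent <- sc$zones_by_level[["2"]]$zones
  res$coarse <- parent$parent_id[match(res$zone_id, parent$zone_id)]
  sums <- tapply(res$residual, res$coarse, sum)
  scale <- tapply(res$observed, res$coarse, sum)
  expect_true(all(abs(sums) / scale < 1e-6))
})

test_that("single-year M1 and M2 produce identical surfaces", {
  sc <- default_scene()
  spec1 <- scheme_spec("M1", years = 1989L, training_year = 1989L,
                       training_level = 2L, evaluation_level = 2L,
                       redistribution_level = 1L)
  spec2 <- scheme_spec("M2", years = 1989L, training_level = 2L,
                       evaluation_level = 2L, redistribution_level = 1L)
  out1 <- run_m1(sc, spec1, hyperparams = rf_params(trees = 100), seed = 7)
  out2 <- run_m2(sc, spec2, hyperparams = rf_params(trees = 100), seed = 7)
  expect_identical(out1[["1989"]]$people_per_cell$values,
                   out2[["1989"]]$people_per_cell$values)
})

test_that("identical stacks across years give identical M1 weight shares", {
  sc <- default_scene()
  frozen <- sc
  first <- frozen$builtup_by_epoch[[1]]
  for (nm in names(frozen$builtup_by_epoch)) {
    frozen$builtup_by_epoch[[nm]] <- first
  }
  spec <- scheme_spec("M1", years = c(1979L, 2009L), training_year = 1979L,
                      training_level = 3L, evaluation_level = 2L,
                      redistribution_level = 1L)
  out <- run_m1(frozen, spec, hyperparams = rf_params(trees = 100), seed = 1)
  # same weights + conservation => per-cell shares of the zone count match
  c79 <- aggregate_truth(out[["1979"]], frozen$zones_by_level[["1"]])
  c09 <- aggregate_truth(out[["2009"]], frozen$zones_by_level[["1"]])
  lab <- as.vector(frozen$zones_by_level[["1"]]$labels$values)
  share <- function(surface, totals) {
    as.vector(surface$people_per_cell$values) /
      totals$population[match(lab, totals$zone_id)]
  }
  expect_equal(share(out[["1979"]], c79), share(out[["2009"]], c09),
               tolerance = 1e-12)
})

test_that("seeded scheme runs are reproducible", {
  sc <- default_scene()
  spec <- scheme_spec("M2", years = c(1979L, 1989L), training_level = 2L,
                      evaluation_level = 2L, redistribution_level = 1L)
  a <- run_m2(sc, spec, hyperparams = rf_params(trees = 80), seed = 5)
  b <- run_m2(sc, spec, hyperparams = rf_params(trees = 80), seed = 5)
  expect_identical(a[["1979"]]$people_per_cell$values,
                   b[["1979"]]$people_per_cell$values)
  expect_identical(a[["1989"]]$people_per_cell$values,
                   b[["1989"]]$people_per_cell$values)
})

test_that("scheme comparison picks winners, ties and metric disagreements", {
  rep_of <- function(m1_rmse, m1_mae, m2_rmse, m2_mae, year = 1979L) {
    tibble::tibble(
      scheme = c("M1", "M2"), year = year,
      rmse = c(m1_rmse, m2_rmse), mae = c(m1_mae, m2_mae),
      n_units = 10L, residuals = list(NULL, NULL)
    )
  }
  # clear M1 win
  cmp <- compare_schemes(rep_of(5, 4, 7, 6))
  expect_equal(cmp$rmse_winner, "M1")
  expect_equal(cmp$mae_winner, "M1")
  expect_false(cmp$metrics_disagree)
  # identical -> tie, flagged
  cmp_tie <- compare_schemes(rep_of(5, 4, 5, 4))
  expect_equal(cmp_tie$rmse_winner, "tie")
  expect_true(cmp_tie$metrics_disagree)
  # metrics disagree -> flagged
  cmp_dis <- compare_schemes(rep_of(5, 9, 7, 6))
  expect_equal(cmp_dis$rmse_winner, "M1")
  expect_equal(cmp_dis$mae_winner, "M2")
  expect_true(cmp_dis$metrics_disagree)
  # mismatched year sets error
  bad <- dplyr::bind_rows(rep_of(5, 4, 7, 6),
                          rep_of(5, 4, 7, 6, year = 1989L)[1, ])
  expect_error(compare_schemes(bad), "different year sets")
})

test_that("scheme specs validate their level and year requirements", {
  expect_error(scheme_spec("M1", years = 1979L, evaluation_level = 1L,
                           redistribution_level = 2L, training_year = 1979L),
               "strictly coarser")
  expect_error(scheme_spec("M1", years = 1979L), "training_year")
})

test_that("growth summaries match closed forms and the coastal census totals", {
  # historical study-area totals: ratio > 2.5 over 1979-2009
  totals <- utils::read.csv(system.file("extdata",
                                        "kenya_coast_census_totals.csv",
                                        package = "popdasym"))
  g <- growth_summary(totals[, c("year", "population")])
  tot <- g[g$zone_id == "TOTAL", ]
  expect_equal(tot$ratio, 2679478 / 1014567)
  expect_gt(tot$ratio, 2.5)
  expect_equal(tot$ratio, 2.641, tolerance = 1e-3)

  # constant population: ratio 1, rate 0
  cst <- growth_summary(tibble::tibble(year = c(2000, 2010),
                                       population = c(5, 5)))
  expect_equal(cst$ratio[cst$zone_id == "TOTAL"], 1)
  expect_equal(cst$annual_rate[cst$zone_id == "TOTAL"], 0)

  # doubling over 10 years: r = 2^(1/10) - 1
  dbl <- growth_summary(tibble::tibble(year = c(2000, 2010),
                                       population = c(100, 200)))
  expect_equal(dbl$annual_rate[dbl$zone_id == "TOTAL"], 2^(1 / 10) - 1)
  expect_equal(dbl$annual_rate[dbl$zone_id == "TOTAL"], 0.0718,
               tolerance = 1e-3)

  # zero first-year total flagged, not an error
  z <- growth_summary(tibble::tibble(zone_id = c("a", "a", "b", "b"),
                                     year = c(2000, 2010, 2000, 2010),
                                     population = c(0, 5, 1, 2)))
  expect_true(z$flagged[z$zone_id == "a"])
  expect_true(is.na(z$ratio[z$zone_id == "a"]))
  expect_error(growth_summary(tibble::tibble(year = 2000, population = 1)),
               "two census years")
})
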