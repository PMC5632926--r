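#' Specify a training scheme for multi-year disaggregation
#'
#' Two ways to train density models across census years:
#' \describe{
#'   \item{M1}{one model fitted on the single year with the most spatially
#'     detailed census data (`training_year` at `training_level`), then
#'     transferred to every year — assumes covariate--density relationships
#'     are stable over time;}
#'   \item{M2}{an independent model per year, each trained on that year's
#'     census at `training_level` — tracks changing relationships at the
#'     cost of coarser training data.}
#' }
#' Evaluation always redistributes counts from a coarse
#' `redistribution_level` and scores the result against held census data at
#' the strictly finer `evaluation_level`.
#'
#' @param scheme `"M1"` or `"M2"`.
#' @param years Integer census years to produce surfaces for.
#' @param training_level Admin level used for model training (1 = coarsest).
#' @param evaluation_level Admin level whose census data scores the output.
#' @param redistribution_level Coarse level whose counts are redistributed;
#'   must be strictly coarser (smaller) than `evaluation_level`.
#' @param training_year Year of the training census (required for M1;
#'   ignored for M2).
#' @return A `scheme_spec` list.
#' @export
scheme_spec <- function(scheme = c("M1", "M2"), years,
                        training_level = 3L, evaluation_level = 2L,
                        redistribution_level = 1L, training_year = NULL) {
  scheme <- match.arg(scheme)
  if (redistribution_level >= evaluation_level) {
    stop("redistribution level must be strictly coarser than evaluation level",
         call. = FALSE)
  }
  if (scheme == "M1") {
    if (is.null(training_year)) {
      stop("M1 requires a training_year", call. = FALSE)
    }
  }
  structure(list(
    scheme = scheme, years = as.integer(years),
    training_level = as.integer(training_level),
    evaluation_level = as.integer(evaluation_level),
    redistribution_level = as.integer(redistribution_level),
    training_year = if (is.null(training_year)) NULL else as.integer(training_year)
  ), class = "scheme_spec")
}

# shared plumbing: stacks, mask, zonal tables, redistribution counts
scheme_env <- function(scene, spec, buffer_distance, class_codes) {
  years <- unique(c(spec$years, spec$training_year))
  mask <- build_exclusion_mask(scene$protected_mask, scene$road_mask,
                               scene$coastline_mask, buffer_distance)
  stacks <- stats::setNames(
    lapply(years, function(y) build_stack(scene, y, class_codes = class_codes)),
    as.character(years)
  )
  # coarse counts for redistribution derive from the evaluation-level census
  # aggregated upward, so predicted and observed coarse totals coincide
  eval_zones <- scene$zones_by_level[[as.character(spec$evaluation_level)]]
  red_zones <- scene$zones_by_level[[as.character(spec$redistribution_level)]]
  parent_chain <- function(level_from, level_to) {
    map <- stats::setNames(
      scene$zones_by_level[[as.character(level_from)]]$zones$zone_id,
      scene$zones_by_level[[as.character(level_from)]]$zones$zone_id
    )
    lv <- level_from
    out <- as.integer(names(map))
    res <- stats::setNames(as.integer(map), names(map))
    while (lv > level_to) {
      ztab <- scene$zones_by_level[[as.character(lv)]]$zones
      up <- stats::setNames(ztab$parent_id, ztab$zone_id)
      res <- stats::setNames(up[as.character(res)], names(res))
      lv <- lv - 1L
    }
    res
  }
  up_map <- parent_chain(spec$evaluation_level, spec$redistribution_level)
  red_census <- function(year) {
    ev <- get_census(scene, spec$evaluation_level, year)
    agg <- rowsum(ev$population, group = up_map[as.character(ev$zone_id)])
    tibble::tibble(
      zone_id = as.integer(rownames(agg)),
      level = spec$redistribution_level,
      year = as.integer(year),
      population = agg[, 1]
    )
  }
  list(mask = mask, stacks = stacks, eval_zones = eval_zones,
       red_zones = red_zones, red_census = red_census)
}

fit_for_year <- function(scene, env, level, year, hyperparams, seed) {
  zones <- scene$zones_by_level[[as.character(level)]]
  stack <- env$stacks[[as.character(year)]]
  zt <- zonal_aggregate(stack, zones)
  areas <- zone_areas(zones, env$mask)
  census <- get_census(scene, level, year)
  fit_density_model(zt, census, areas, hyperparams = hyperparams, seed = seed)
}

#' Run the M1 scheme: one model transferred to all years
#'
#' Fits a single density model on `training_year` at `training_level`, then
#' for every requested year predicts that year's weighting surface from the
#' year's own covariate stack and redistributes the coarse counts (obtained
#' by aggregating the evaluation-level census upward).
#'
#' @param scene A `synthetic_scene` (or scene-shaped list).
#' @param spec A [scheme_spec()] with `scheme = "M1"`.
#' @param hyperparams An [rf_params()].
#' @param buffer_distance Exclusion buffer around roads and coastline.
#' @param class_codes Land-cover codes expanded in the stacks.
#' @param seed Forest seed.
#' @return Named list `year -> population_surface`; the fitted model in
#'   attribute `"models"`.
#' @export
run_m1 <- function(scene, spec, hyperparams = rf_params(),
                   buffer_distance = 200, class_codes = 1:9, seed = 1L) {
  stopifnot(spec$scheme == "M1")
  env <- scheme_env(scene, spec, buffer_distance, class_codes)
  model <- fit_for_year(scene, env, spec$training_level, spec$training_year,
                        hyperparams, seed)
  out <- lapply(spec$years, function(y) {
    ws <- predict_weight_surface(model, env$stacks[[as.character(y)]], env$mask)
    dasymetric_redistribute(ws, env$red_zones, env$red_census(y))
  })
  out <- stats::setNames(out, as.character(spec$years))
  attr(out, "models") <- stats::setNames(list(model),
                                         as.character(spec$training_year))
  out
}

#' Run the M2 scheme: an independent model per year
#'
#' Each year's model trains on that year's census at `training_level` and
#' predicts only its own year. Per-year forests draw seeds from a common
#' stream (`seed + year index`) so runs are reproducible without coupling
#' years.
#'
#' @inheritParams run_m1
#' @param spec A [scheme_spec()] with `scheme = "M2"`.
#' @return Named list `year -> population_surface`; fitted models in
#'   attribute `"models"`.
#' @export
run_m2 <- function(scene, spec, hyperparams = rf_params(),
                   buffer_distance = 200, class_codes = 1:9, seed = 1L) {
  stopifnot(spec$scheme == "M2")
  env <- scheme_env(scene, spec, buffer_distance, class_codes)
  models <- list()
  out <- lapply(seq_along(spec$years), function(i) {
    y <- spec$years[i]
    model <- fit_for_year(scene, env, spec$training_level, y,
                          hyperparams, seed + i - 1L)
    models[[as.character(y)]] <<- model
    ws <- predict_weight_surface(model, env$stacks[[as.character(y)]], env$mask)
    dasymetric_redistribute(ws, env$red_zones, env$red_census(y))
  })
  out <- stats::setNames(out, as.character(spec$years))
  attr(out, "models") <- models
  out
}

#' Validate a surface by reaggregation against finer census data
#'
#' Sums the gridded prediction within each reference zone and scores the
#' per-zone residuals (predicted minus observed count) with RMSE and MAE.
#'
#' @param surface A `population_surface`.
#' @param reference_zones [admin_zones()] at the evaluation level.
#' @param reference_census Census tibble (`zone_id`, `population`) for those
#'   zones.
#' @return One-row tibble `rmse`, `mae`, `n_units`, plus a `residuals`
#'   list-column holding the per-zone tibble (`zone_id`, `observed`,
#'   `predicted`, `residual`).
#' @export
validate_by_reaggregation <- function(surface, reference_zones,
                                      reference_census) {
  pred <- aggregate_truth(surface, reference_zones)
  missing <- setdiff(reference_census$zone_id, pred$zone_id)
  if (length(missing) > 0) {
    stop(sprintf("census zones absent from reference zones: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  d <- dplyr::inner_join(
    dplyr::select(reference_census, "zone_id", observed = "population"),
    dplyr::select(pred, "zone_id", predicted = "population"),
    by = "zone_id"
  )
  d$residual <- d$predicted - d$observed
  tibble::tibble(
    rmse = sqrt(mean(d$residual^2)),
    mae = mean(abs(d$residual)),
    n_units = nrow(d),
    residuals = list(d)
  )
}

#' Score both schemes' surfaces against evaluation census data
#'
#' @param surfaces_by_scheme Named list `scheme -> (year -> surface)` as
#'   returned by [run_m1()]/[run_m2()].
#' @param scene The scene supplying evaluation zones and census tables.
#' @param evaluation_level Admin level to validate against.
#' @return A validation report tibble: `scheme`, `year`, `rmse`, `mae`,
#'   `n_units`, `residuals` (list-column).
#' @export
validate_schemes <- function(surfaces_by_scheme, scene, evaluation_level = 2L) {
  zones <- scene$zones_by_level[[as.character(evaluation_level)]]
  dplyr::bind_rows(lapply(names(surfaces_by_scheme), function(sch) {
    surfaces <- surfaces_by_scheme[[sch]]
    dplyr::bind_rows(lapply(names(surfaces), function(y) {
      census <- get_census(scene, evaluation_level, as.integer(y))
      v <- validate_by_reaggregation(surfaces[[y]], zones, census)
      dplyr::mutate(v, scheme = sch, year = as.integer(y), .before = 1)
    }))
  }))
}

#' Per-year winner table for two schemes
#'
#' Compares RMSE and MAE between the two schemes year by year and flags
#' years where the two metrics disagree about the winner (or tie).
#'
#' @param report Validation report tibble from [validate_schemes()]
#'   containing exactly two schemes scored on identical year sets.
#' @return Tibble `year`, `rmse_winner`, `mae_winner`, `metrics_disagree`.
#' @export
compare_schemes <- function(report) {
  schemes <- sort(unique(report$scheme))
  if (length(schemes) != 2) {
    stop("report must contain exactly two schemes", call. = FALSE)
  }
  a <- schemes[1]; b <- schemes[2]
  ya <- sort(report$year[report$scheme == a])
  yb <- sort(report$year[report$scheme == b])
  if (!identical(ya, yb)) {
    stop("schemes were scored on different year sets", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(report, "scheme", "year", "rmse", "mae"),
    names_from = "scheme", values_from = c("rmse", "mae")
  )
  pick <- function(va, vb) {
    dplyr::case_when(va < vb ~ a, vb < va ~ b, TRUE ~ "tie")
  }
  out <- tibble::tibble(
    year = wide$year,
    rmse_winner = pick(wide[[paste0("rmse_", a)]], wide[[paste0("rmse_", b)]]),
    mae_winner = pick(wide[[paste0("mae_", a)]], wide[[paste0("mae_", b)]])
  )
  out$metrics_disagree <- out$rmse_winner != out$mae_winner |
    out$rmse_winner == "tie"
  out
}

#' Population totals, growth ratios and annualized growth rates
#'
#' For each zone and for the domain total: population at the first and last
#' year, their ratio, and the average annual growth rate
#' `r = (P_last / P_first)^(1 / (y_last - y_first)) - 1`.
#'
#' @param census Tibble with columns `zone_id` (or none, treated as one
#'   zone), `year`, `population`; typically one admin level's tables across
#'   years.
#' @return Tibble `zone_id` (with a final `"TOTAL"` row), `first_year`,
#'   `last_year`, `p_first`, `p_last`, `ratio`, `annual_rate`, `flagged`
#'   (`TRUE` when the first-year total is zero and the ratio undefined).
#' @examples
#' growth_summary(tibble::tibble(year = c(1979, 2009),
#'                               population = c(1014567, 2679478)))
#' @export
growth_summary <- function(census) {
  census <- tibble::as_tibble(census)
  if (!"zone_id" %in% names(census)) census$zone_id <- "domain"
  if (length(unique(census$year)) < 2) {
    stop("need at least two census years", call. = FALSE)
  }
  one <- function(d, id) {
    d <- d[order(d$year), ]
    y1 <- d$year[1]; y2 <- d$year[nrow(d)]
    p1 <- sum(d$population[d$year == y1])
    p2 <- sum(d$population[d$year == y2])
    ratio <- if (p1 > 0) p2 / p1 else NA_real_
    tibble::tibble(
      zone_id = as.character(id), first_year = y1, last_year = y2,
      p_first = p1, p_last = p2, ratio = ratio,
      annual_rate = if (!is.na(ratio)) ratio^(1 / (y2 - y1)) - 1 else NA_real_,
      flagged = p1 <= 0
    )
  }
  per_zone <- dplyr::bind_rows(lapply(split(census, census$zone_id),
                                      function(d) one(d, d$zone_id[1])))
  total <- one(census, "TOTAL")
  dplyr::bind_rows(per_zone, total)
}
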