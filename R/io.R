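#' Read and validate a census CSV
#'
#' Expects the header `zone_id,level,year,population` (extra columns kept).
#' Validation is itemized: duplicate ids within a (level, year), negative
#' populations, and — when a zone set is supplied — census ids absent from
#' it are each reported.
#'
#' @param path CSV path.
#' @param zones Optional [admin_zones()] to cross-check zone ids against.
#' @return A census tibble.
#' @export
read_census <- function(path, zones = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("census file not found: %s", path), call. = FALSE)
  }
  tab <- tibble::as_tibble(utils::read.csv(path))
  need <- c("zone_id", "level", "year", "population")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop(sprintf("census file %s missing columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  problems <- character(0)
  dup <- tab |>
    dplyr::count(.data$zone_id, .data$level, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    problems <- c(problems, sprintf(
      "duplicate zone_id within (level, year): %s",
      paste(utils::head(dup$zone_id, 5), collapse = ", ")
    ))
  }
  neg <- tab$zone_id[tab$population < 0]
  if (length(neg) > 0) {
    problems <- c(problems, sprintf(
      "negative population for zone_id: %s",
      paste(utils::head(neg, 5), collapse = ", ")
    ))
  }
  if (!is.null(zones)) {
    unknown <- setdiff(tab$zone_id, zones$zones$zone_id)
    if (length(unknown) > 0) {
      problems <- c(problems, sprintf(
        "zone_id absent from zone set: %s",
        paste(utils::head(unknown, 5), collapse = ", ")
      ))
    }
  }
  if (length(problems) > 0) {
    stop(paste0("invalid census table:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  tab
}

#' @rdname read_census
#' @param census Census tibble to write.
#' @export
write_census <- function(census, path) {
  utils::write.csv(census, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything `run_pipeline()` needs: a scene source (either a
#' [scene_config()] to simulate or a directory to read), the exclusion
#' buffer, forest hyperparameters, scheme settings and the output directory.
#'
#' @param scene_config A [scene_config()], or `NULL` when `scene_dir` is
#'   given.
#' @param scene_dir Directory with a serialized scene (see [write_scene()]).
#' @param out_dir Output directory for surfaces, reports and the manifest.
#' @param buffer_distance Exclusion buffer (length units, default 200).
#' @param hyperparams An [rf_params()].
#' @param years Census years to produce; default: all years in the scene.
#' @param training_year M1 training year; default: the year with census
#'   data at the finest level (largest level number) in the scene.
#' @param training_level_m1,training_level_m2 Admin levels for training.
#' @param evaluation_level,redistribution_level Validation geometry.
#' @param final_scheme Which scheme's surfaces are written as the final
#'   maps; default `"M1"`.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scene_config = NULL, scene_dir = NULL,
                            out_dir = "popdasym_out",
                            buffer_distance = 200,
                            hyperparams = rf_params(),
                            years = NULL, training_year = NULL,
                            training_level_m1 = 3L, training_level_m2 = 2L,
                            evaluation_level = 2L, redistribution_level = 1L,
                            final_scheme = c("M1", "M2"), seed = 1L) {
  if (is.null(scene_config) && is.null(scene_dir)) {
    stop("provide a scene_config or a scene_dir", call. = FALSE)
  }
  if (!is.null(scene_dir) && !dir.exists(scene_dir)) {
    stop(sprintf("scene directory not found: %s", scene_dir), call. = FALSE)
  }
  if (buffer_distance < 0) stop("buffer_distance must be >= 0", call. = FALSE)
  structure(list(
    scene_config = scene_config, scene_dir = scene_dir, out_dir = out_dir,
    buffer_distance = buffer_distance, hyperparams = hyperparams,
    years = years, training_year = training_year,
    training_level_m1 = as.integer(training_level_m1),
    training_level_m2 = as.integer(training_level_m2),
    evaluation_level = as.integer(evaluation_level),
    redistribution_level = as.integer(redistribution_level),
    final_scheme = match.arg(final_scheme), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full pipeline: simulate/load, fit, redistribute, validate, compare
#'
#' Executes the end-to-end flow — scene, covariate stacks, M1 and M2
#' models, weighting surfaces, mass-conserving redistribution, validation
#' by reaggregation, scheme comparison and growth summary — and writes the
#' artifacts (`final_<scheme>_<year>.asc` surfaces, `validation.csv`,
#' `comparison.csv`, `growth.csv`, `manifest.json`) to the configured output
#' directory. The manifest records the seed, a hash of the configuration
#' and a hash per output file, so identical config + seed reproduce an
#' identical manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report`, `comparison`, `growth`,
#'   `surfaces`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  scene <- if (!is.null(config$scene_dir)) {
    read_scene(config$scene_dir)
  } else {
    generate_scene(config$scene_config)
  }
  years <- config$years %||% scene$meta$config$census_years
  training_year <- config$training_year %||% years[min(3, length(years))]

  m1_spec <- scheme_spec("M1", years = years,
                         training_level = config$training_level_m1,
                         evaluation_level = config$evaluation_level,
                         redistribution_level = config$redistribution_level,
                         training_year = training_year)
  m2_spec <- scheme_spec("M2", years = years,
                         training_level = config$training_level_m2,
                         evaluation_level = config$evaluation_level,
                         redistribution_level = config$redistribution_level)
  m1 <- run_m1(scene, m1_spec, hyperparams = config$hyperparams,
               buffer_distance = config$buffer_distance, seed = config$seed)
  m2 <- run_m2(scene, m2_spec, hyperparams = config$hyperparams,
               buffer_distance = config$buffer_distance, seed = config$seed)
  report <- validate_schemes(list(M1 = m1, M2 = m2), scene,
                             evaluation_level = config$evaluation_level)
  comparison <- compare_schemes(report)
  growth <- growth_summary(
    get_all_years(scene, config$redistribution_level, years)
  )

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  final <- if (config$final_scheme == "M1") m1 else m2
  for (y in names(final)) {
    write_raster(final[[y]]$people_per_cell,
                 file.path(config$out_dir,
                           sprintf("final_%s_%s.asc", config$final_scheme, y)))
  }
  utils::write.csv(
    dplyr::select(report, "scheme", "year", "rmse", "mae", "n_units"),
    file.path(config$out_dir, "validation.csv"), row.names = FALSE
  )
  utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(growth, file.path(config$out_dir, "growth.csv"),
                   row.names = FALSE)

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "popdasym",
    version = as.character(utils::packageVersion("popdasym")),
    seed = config$seed,
    final_scheme = config$final_scheme,
    config_hash = rlang::hash(config),
    outputs = stats::setNames(
      lapply(files, function(f) rlang::hash(readLines(f, warn = FALSE))),
      basename(files)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, comparison = comparison, growth = growth,
                 surfaces = list(M1 = m1, M2 = m2), manifest = manifest))
}

# all years' census at one level, stacked
get_all_years <- function(scene, level, years) {
  dplyr::bind_rows(lapply(years, function(y) get_census(scene, level, y)))
}
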