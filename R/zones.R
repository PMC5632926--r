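#' Administrative zone sets
#'
#' An `admin_zones` object is a label-raster partition of the domain at one
#' administrative level, together with a zone table linking each zone to its
#' parent at the next coarser level. Nested hierarchies (district ->
#' sub-location -> enumeration-area style) are represented as one
#' `admin_zones` per level sharing the same grid geometry.
#'
#' @param labels A [raster_grid()] of integer zone ids (> 0); every cell
#'   belongs to exactly one zone.
#' @param zones A tibble with columns `zone_id`, `parent_id` (`NA` at the
#'   coarsest level) and `level` (integer; larger = finer).
#'
#' @return An object of class `admin_zones`.
#' @export
admin_zones <- function(labels, zones) {
  stopifnot(inherits(labels, "raster_grid"))
  zones <- tibble::as_tibble(zones)
  need <- c("zone_id", "parent_id", "level")
  if (!all(need %in% names(zones))) {
    stop("`zones` must have columns zone_id, parent_id, level", call. = FALSE)
  }
  if (anyDuplicated(zones$zone_id)) {
    stop("duplicate zone_id in zone table", call. = FALSE)
  }
  present <- unique(as.vector(labels$values))
  missing <- setdiff(present, zones$zone_id)
  if (length(missing) > 0) {
    stop(sprintf("label raster contains ids absent from zone table: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(labels = labels, zones = zones), class = "admin_zones")
}

#' @export
print.admin_zones <- function(x, ...) {
  cat(sprintf("<admin_zones> level %d: %d zones on a %d x %d grid\n",
              x$zones$level[1], nrow(x$zones),
              nrow(x$labels$values), ncol(x$labels$values)))
  invisible(x)
}

#' Number of zones in an admin_zones object
#' @param zones An [admin_zones()] object.
#' @return Integer count.
#' @export
n_zones <- function(zones) nrow(zones$zones)

# list of cell indices per zone_id (names are zone ids)
zone_cells <- function(zones) {
  split(seq_along(zones$labels$values), as.vector(zones$labels$values))
}

#' Aggregate one admin level up to its parents
#'
#' Produces the coarser-level `admin_zones` implied by the `parent_id`
#' links: each cell takes its zone's parent id.
#'
#' @param fine An [admin_zones()] object whose `parent_id` column is filled.
#' @param parent_table Optional tibble (`zone_id`, `parent_id`, `level`) for
#'   the parent level; if omitted, parents get `parent_id = NA` and
#'   `level = level - 1`.
#' @return An [admin_zones()] at the parent level.
#' @export
coarsen_zones <- function(fine, parent_table = NULL) {
  map <- stats::setNames(fine$zones$parent_id, fine$zones$zone_id)
  if (anyNA(map)) {
    stop("cannot coarsen: parent_id has missing values", call. = FALSE)
  }
  lab <- fine$labels
  parent_vals <- matrix(as.integer(map[as.character(lab$values)]),
                        nrow(lab$values), ncol(lab$values))
  labels <- raster_grid(parent_vals, lab$origin_x, lab$origin_y,
                        lab$cell_size, lab$nodata)
  if (is.null(parent_table)) {
    parent_table <- tibble::tibble(
      zone_id = sort(unique(fine$zones$parent_id)),
      parent_id = NA_integer_,
      level = fine$zones$level[1] - 1L
    )
  }
  admin_zones(labels, parent_table)
}

#' Read and write admin zones (label raster + zone-table CSV)
#'
#' The label raster is stored as an Esri ASCII grid (`<stem>.asc`) and the
#' zone table as CSV (`<stem>.csv`) with header `zone_id,parent_id,level`.
#'
#' @param stem Path stem (without extension).
#' @param zones An [admin_zones()] to write.
#' @return `read_zones()` returns an [admin_zones()]; `write_zones()` the
#'   stem, invisibly.
#' @export
read_zones <- function(stem) {
  csv <- paste0(stem, ".csv")
  asc <- paste0(stem, ".asc")
  if (!file.exists(csv)) stop(sprintf("zone table not found: %s", csv), call. = FALSE)
  tab <- utils::read.csv(csv)
  admin_zones(read_raster(asc), tibble::as_tibble(tab))
}

#' @rdname read_zones
#' @export
write_zones <- function(zones, stem) {
  lab <- zones$labels
  lab$values <- matrix(as.integer(lab$values), nrow(lab$values), ncol(lab$values))
  write_raster(lab, paste0(stem, ".asc"))
  utils::write.csv(zones$zones, paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Zone areas net of an exclusion mask
#'
#' Area of each zone counted over unmasked cells only, in squared length
#' units. This is the denominator used for the model's population-density
#' response: people are defined to live only on unmasked cells, so the
#' training density and the prediction support use the same area measure.
#'
#' @param zones An [admin_zones()] object.
#' @param mask Binary [raster_grid()] of excluded cells (1 = excluded), or
#'   `NULL` for no exclusion.
#' @return A tibble with `zone_id`, `n_cells`, `n_unmasked`, `area`
#'   (unmasked cells x cell area).
#' @export
zone_areas <- function(zones, mask = NULL) {
  lab <- as.vector(zones$labels$values)
  cell_area <- zones$labels$cell_size^2
  keep <- if (is.null(mask)) {
    rep(TRUE, length(lab))
  } else {
    stopifnot_coregistered(zones$labels, mask, "zones and mask")
    as.vector(mask$values) == 0
  }
  all_ids <- zones$zones$zone_id
  n_cells <- tabulate(match(lab, all_ids), nbins = length(all_ids))
  n_unmasked <- tabulate(match(lab[keep], all_ids), nbins = length(all_ids))
  tibble::tibble(
    zone_id = all_ids,
    n_cells = n_cells,
    n_unmasked = n_unmasked,
    area = n_unmasked * cell_area
  )
}
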