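#' Plot a raster grid
#'
#' @param object A [raster_grid()].
#' @param trans Optional scale transform for the fill (e.g. `"log1p"` for
#'   skewed population surfaces).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.raster_grid <- function(object, trans = "identity", ...) {
  d <- as_tibble.raster_grid(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.raster_grid
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.population_surface <- function(object, trans = "log1p", ...) {
  autoplot.raster_grid(object$people_per_cell, trans = trans) +
    ggplot2::labs(fill = "people / cell")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of scheme accuracy by year
#'
#' Side-by-side RMSE and MAE for the two training schemes across census
#' years — the standard way to see which scheme wins where, and whether the
#' two metrics agree.
#'
#' @param report Validation report tibble from [validate_schemes()].
#' @return A ggplot object.
#' @export
plot_scheme_comparison <- function(report) {
  d <- tidyr::pivot_longer(
    dplyr::select(report, "scheme", "year", "rmse", "mae"),
    cols = c("rmse", "mae"), names_to = "metric", values_to = "value"
  )
  d$metric <- toupper(d$metric)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$year), y = .data$value,
                                  fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "census year", y = "error (people per unit)",
                  fill = "scheme") +
    ggplot2::theme_minimal()
}

#' Dot plot of permutation covariate importance
#'
#' @param importance Tibble from [covariate_importance()], or a named list
#'   of such tibbles (one per year) to compare importance stability across
#'   year-specific models.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  if (!is.data.frame(importance)) {
    importance <- dplyr::bind_rows(importance, .id = "year")
  }
  p <- ggplot2::ggplot(importance,
                       ggplot2::aes(x = .data$pct_increase_mse,
                                    y = stats::reorder(.data$covariate,
                                                       .data$pct_increase_mse))) +
    ggplot2::labs(x = "% increase in OOB MSE when permuted", y = NULL) +
    ggplot2::theme_minimal()
  if ("year" %in% names(importance)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$year), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
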