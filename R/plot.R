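#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# long tibble of one matrix with map coordinates
grid_to_long <- function(values, origin_x, origin_y, cell_size) {
  nr <- nrow(values); nc <- ncol(values)
  tibble::tibble(
    x = origin_x + (rep(seq_len(nc), each = nr) - 0.5) * cell_size,
    y = origin_y - (rep(seq_len(nr), times = nc) - 0.5) * cell_size,
    value = as.vector(values)
  )
}

#' Plot a relative frequency-of-use map
#'
#' Pixels are shaded by relative frequency of use (visit count divided by
#' the most-used pixel's count); never-used pixels are drawn white, as on
#' the connectivity maps.
#'
#' @param object A `usage_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usage_map <- function(object, ...) {
  rel <- relative_frequency(object)
  df <- grid_to_long(rel$values, object$origin_x, object$origin_y,
                     object$cell_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "relative\nfrequency") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("Relative frequency of use (%s)",
                                  object$scenario)) +
    ggplot2::theme_minimal()
}

#' Plot the layers of a landscape as one categorical map
#'
#' Shows open habitat, escape terrain, movement-blocking crown cover,
#' water, and roads in a single view; barriers draw over terrain.
#'
#' @param object A `raster_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.raster_landscape <- function(object, ...) {
  cls <- matrix("open", object$n_rows, object$n_cols)
  cls[object$cover$values > object$rules$cover_threshold_pct] <- "dense cover"
  cls[object$escape] <- "escape terrain"
  cls[object$water_mask] <- "water"
  cls[object$road_mask] <- "road"
  cls[object$nodata_mask] <- NA
  df <- grid_to_long(cls, object$origin_x, object$origin_y,
                     object$cell_size)
  pal <- c("open" = "wheat", "escape terrain" = "grey30",
           "dense cover" = "darkgreen", "water" = "steelblue",
           "road" = "black")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, na.value = "white",
                               name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a single agent trajectory
#'
#' @param object An `hw_trajectory` from [run_agent()].
#' @param landscape Optional `raster_landscape` drawn underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hw_trajectory <- function(object, landscape = NULL, ...) {
  p <- if (is.null(landscape)) {
    ggplot2::ggplot() + ggplot2::coord_equal()
  } else autoplot(landscape)
  p +
    ggplot2::geom_path(data = object,
                       ggplot2::aes(.data$x, .data$y), colour = "red") +
    ggplot2::geom_point(data = object[1, ],
                        ggplot2::aes(.data$x, .data$y), colour = "red",
                        size = 2) +
    ggplot2::labs(
      subtitle = sprintf("%d moves, removed: %s", nrow(object) - 1L,
                         attr(object, "removal_reason")))
}
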