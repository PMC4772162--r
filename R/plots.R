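#' Map per-cell values over the grid
#'
#' @param grid a [make_grid()] domain.
#' @param values numeric vector ordered by `cell_id`, or a tibble with
#'   `cell_id` and one value column.
#' @param name legend title.
#' @return a ggplot tile map.
#' @export
plot_grid_values <- function(grid, values, name = "value") {
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values), "cell_id")[1]
    values <- values[[vcol]][match(grid$cell_id, values$cell_id)]
    if (missing(name)) name <- vcol
  }
  d <- tibble(lon = grid$lon, lat = grid$lat, value = values)
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Map stacked-SDM species richness
#'
#' @param pa a `pa_matrix`.
#' @param grid the grid (taken from `pa` if stored there).
#' @return a ggplot tile map of per-cell richness.
#' @export
plot_richness <- function(pa, grid = pa$grid) {
  if (is.null(grid)) abort("supply `grid`")
  plot_grid_values(grid, richness(pa), name = "richness")
}

#' Map region labels
#'
#' @param x a `regionalization` (or tibble `cell_id`, `region`).
#' @param grid the grid domain.
#' @return a ggplot tile map with one colour per region.
#' @export
plot_regions <- function(x, grid) {
  labels <- if (inherits(x, "regionalization")) x$labels else x
  d <- dplyr::inner_join(as_tibble(grid)[c("cell_id", "lon", "lat")],
                         labels, by = "cell_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$lon, .data$lat,
                                  fill = factor(.data$region))) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "region") +
    ggplot2::theme_minimal()
}

#' Summed indicator p-value curve over candidate cluster numbers
#'
#' @param x a `regionalization`.
#' @return a ggplot of the mean summed-p curve with the chosen k marked.
#' @export
plot_summed_p <- function(x) {
  ggplot2::ggplot(x$mean_curve, ggplot2::aes(.data$k, .data$summed_p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters",
                  y = "mean summed indicator p-value") +
    ggplot2::theme_minimal()
}

#' Ordination plot with fitted environmental vectors
#'
#' @param object an `ordination`.
#' @param vectors optional [fit_env_vectors()] table; significant vectors
#'   are drawn as arrows scaled by r.
#' @param labels optional tibble `cell_id`, `region` to colour points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ordination
#' @export
autoplot.ordination <- function(object, vectors = NULL, labels = NULL, ...) {
  d <- tibble(cell_id = rownames(object$scores),
              NMDS1 = object$scores[, 1],
              NMDS2 = object$scores[, 2])
  if (!is.null(labels)) {
    labels$cell_id <- as.character(labels$cell_id)
    d <- dplyr::left_join(d, labels, by = "cell_id")
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                         colour = factor(.data$region)))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  }
  p <- p + ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(colour = "region",
                  subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
  if (!is.null(vectors)) {
    v <- dplyr::filter(vectors, .data$significant)
    if (nrow(v) > 0) {
      sc <- 0.9 * max(abs(object$scores[, 1:2]))
      v <- dplyr::mutate(v, x = .data$cos1 * sqrt(.data$r2) * sc,
                         y = .data$cos2 * sqrt(.data$r2) * sc)
      p <- p +
        ggplot2::geom_segment(
          data = v, inherit.aes = FALSE,
          ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
        ggplot2::geom_text(
          data = v, inherit.aes = FALSE,
          ggplot2::aes(.data$x * 1.1, .data$y * 1.1,
                       label = .data$predictor), size = 3)
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
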