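#' Plot methods
#'
#' ggplot2 views of the main result types: cell grids as filled tiles,
#' impact tables as population-by-bin bars, comparison reports as dodged
#' bars, and criticality fields as the road network coloured by score or
#' delta class.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot fa_grid
#' @export
autoplot.fa_grid <- function(object, ...) {
  df <- tidy.fa_grid(object)
  lab <- switch(class(object)[1],
                friction_grid = "min/m", population_grid = "persons",
                time_field = "minutes", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot impact_table
#' @export
autoplot.impact_table <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$population)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "access time to nearest facility", y = "population") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plots
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$label <- factor(df$label, levels = df$label)
  long <- tidyr::pivot_longer(df[, c("label", "pop_raster", "pop_network")],
                              -"label", names_to = "method",
                              names_prefix = "pop_", values_to = "population")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$population,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "access time to nearest facility", y = "population",
                  fill = "engine") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# edge segments of a network joined to a per-edge table
edge_segments <- function(network, table) {
  ed <- network$edges
  ia <- match(ed$node_a, network$nodes$node_id)
  ib <- match(ed$node_b, network$nodes$node_id)
  df <- tibble::tibble(edge_id = ed$edge_id,
                       x = network$nodes$x[ia], y = network$nodes$y[ia],
                       xend = network$nodes$x[ib], yend = network$nodes$y[ib])
  dplyr::left_join(df, tibble::as_tibble(unclass(table)), by = "edge_id")
}

#' Plot TEBC scores on the road network
#'
#' @param field a `tebc_field`.
#' @param network the [road_network()] the graph was built from.
#' @return A ggplot object.
#' @export
plot_tebc <- function(field, network) {
  df <- edge_segments(network, field)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_segment(ggplot2::aes(colour = .data$score,
                                       linewidth = .data$score)) +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  colour = "TEBC") +
    ggplot2::theme_minimal()
}

#' Plot the criticality delta classification
#'
#' @param delta an `edge_criticality` from [tebc_delta()].
#' @param network the [road_network()].
#' @return A ggplot object.
#' @export
plot_criticality_delta <- function(delta, network) {
  df <- edge_segments(network, delta)
  pal <- c(FLOODED = "#2166ac", LOST = "#b2182b", DECREASED = "#ef8a62",
           UNCHANGED = "grey70", BACKUP_INCREASED = "#1a9850")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend,
                                   colour = .data$class)) +
    ggplot2::geom_segment(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", colour = NULL) +
    ggplot2::theme_minimal()
}
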