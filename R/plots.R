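#' Plot an interaction network
#'
#' Bipartite layout with predators on top, prey below; node size tracks
#' degree.
#'
#' @param object an `interaction_network`.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.interaction_network <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_as_bipartite(g, types = igraph::V(g)$type)
  nodes <- tibble(
    otu_id = igraph::V(g)$name, guild = igraph::V(g)$guild,
    degree = igraph::V(g)$degree, x = lay[, 1], y = lay[, 2]
  )
  ends <- igraph::as_edgelist(g)
  seg <- tibble(
    x = nodes$x[match(ends[, 1], nodes$otu_id)],
    y = nodes$y[match(ends[, 1], nodes$otu_id)],
    xend = nodes$x[match(ends[, 2], nodes$otu_id)],
    yend = nodes$y[match(ends[, 2], nodes$otu_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.2, alpha = 0.4) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$guild, size = .data$degree)) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, size = "connections")
}

#' Plot PCoA sample coordinates
#'
#' @param object a `pcoa_result`.
#' @param colour optional vector of group labels, one per sample.
#' @param ... unused.
#' @return a ggplot of the first two axes.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (ncol(df) < 3) abort("need at least two PCoA axes to plot")
  if (!is.null(colour)) df$group <- colour
  pe <- object$proportion_explained
  lab <- function(i) {
    if (length(pe) >= i) sprintf("axis %d (%.1f%%)", i, 100 * pe[i]) else paste("axis", i)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Plot the cumulative degree distribution
#'
#' @param network an `interaction_network`.
#' @return a ggplot of P(degree >= k) against k (log-scaled y).
#' @export
plot_degree_distribution <- function(network) {
  df <- cumulative_degree_distribution(network)
  ggplot2::ggplot(filter(df, .data$p_geq > 0),
                  ggplot2::aes(x = .data$degree, y = .data$p_geq)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "fraction of nodes with degree >= k") +
    ggplot2::theme_minimal()
}

#' Plot OTU time series
#'
#' Relative-abundance trajectories of selected OTUs, faceted by site and
#' fraction — the view in which predator-prey anti-phase oscillations are
#' visible.
#'
#' @param table an `otu_tbl`.
#' @param otus OTU ids to show.
#' @return a ggplot.
#' @export
plot_series <- function(table, otus) {
  stop_if_not_otu(table)
  df <- filter(as_tibble(table), .data$otu_id %in% otus)
  if (nrow(df) == 0) abort("none of the requested OTUs are in the table")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$count,
                                   colour = .data$otu_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(site ~ fraction) +
    ggplot2::labs(x = NULL, y = if (table_mode(table) == "relative")
      "relative abundance" else "reads", colour = NULL) +
    ggplot2::theme_minimal()
}
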