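#' Plot a species distribution as an incidence tile map
#'
#' @param object A [species_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot species_distribution
#' @export
autoplot.species_distribution <- function(object, ...) {
  df <- tidy(object)
  df$site <- factor(df$site, levels = rev(unique(df$site)))
  df$species <- factor(df$species, levels = unique(df$species))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$site,
                                   fill = factor(.data$present))) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               guide = "none") +
    ggplot2::labs(x = "species", y = "site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-motif value-of-information summaries
#'
#' Mean VoI per motif with its bootstrap interval, motifs ordered by mean.
#'
#' @param object A summary from [summarize_voi_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voi_grid_summary
#' @export
autoplot.voi_grid_summary <- function(object, ...) {
  df <- object
  df$motif <- stats::reorder(df$motif, df$mean_voi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$mean_voi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::labs(x = NULL, y = "value of network information (%)") +
    ggplot2::theme_minimal()
}

#' Plot an actor network
#'
#' Circular layout with line width proportional to the development-link
#' strength and node size proportional to site species richness when a
#' species distribution is supplied.
#'
#' @param object An [actor_network()].
#' @param species Optional [species_distribution()] for node sizes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot actor_network
#' @export
autoplot.actor_network <- function(object, species = NULL, ...) {
  n <- object$n_nodes
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble::tibble(
    node = seq_len(n), x = cos(theta), y = sin(theta),
    label = object$labels %||% as.character(seq_len(n) - 1L),
    richness = if (is.null(species)) 1 else rowSums(species$incidence)
  )
  edges <- object$edges
  if (nrow(edges) > 0) {
    edges$x <- nodes$x[edges$from]
    edges$y <- nodes$y[edges$from]
    edges$xend <- nodes$x[edges$to]
    edges$yend <- nodes$y[edges$to]
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$u_d),
      color = "grey50"
    ) +
      ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none")
  }
  p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, size = .data$richness),
    color = "steelblue"
  ) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$label)) +
    ggplot2::scale_size(range = c(3, 8), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' @export
plot.species_distribution <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.actor_network <- function(x, ...) print(autoplot(x, ...))
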