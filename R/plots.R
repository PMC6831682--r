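# ggplot2 displays for the result types.

#' Plot a fluency network
#'
#' Draws the trial network with a force-directed layout; nodes are coloured
#' by connected component and labelled with their tonal pinyin. When the
#' network carries a stimulus, it is drawn as a diamond with its
#' immediate-neighbour edges dashed.
#'
#' @param object A `fluency_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluency_network <- function(object, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0L) {
    stop("cannot plot an empty network", call. = FALSE)
  }
  stim_label <- if (!is.null(object$stimulus)) object$stimulus$pinyin else NULL
  gp <- g
  stim_edges <- NULL
  if (!is.null(stim_label) && !(stim_label %in% igraph::V(g)$name)) {
    gp <- igraph::add_vertices(gp, 1, name = stim_label)
    neigh <- which(edit_distance(object$stimulus, object$nodes) == 1L)
    if (length(neigh)) {
      gp <- igraph::add_edges(gp, as.vector(rbind(igraph::vcount(gp), neigh)))
    }
  }
  lay <- igraph::layout_with_fr(gp)
  nodes <- tibble::tibble(
    label = igraph::V(gp)$name,
    x = lay[, 1], y = lay[, 2],
    is_stimulus = igraph::V(gp)$name %in% stim_label
  )
  comp <- igraph::components(g)$membership
  nodes$component <- factor(comp[nodes$label])
  el <- igraph::as_edgelist(gp)
  edges <- tibble::tibble(
    from = el[, 1], to = el[, 2],
    x = nodes$x[match(el[, 1], nodes$label)],
    y = nodes$y[match(el[, 1], nodes$label)],
    xend = nodes$x[match(el[, 2], nodes$label)],
    yend = nodes$y[match(el[, 2], nodes$label)],
    stimulus_edge = el[, 1] %in% stim_label | el[, 2] %in% stim_label
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linetype = .data$stimulus_edge),
      colour = "grey50", show.legend = FALSE) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$component,
                   shape = .data$is_stimulus), size = 6,
      show.legend = FALSE) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 2.6, vjust = -1.4) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18)) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed")) +
    ggplot2::theme_void()
}

#' Bar chart of response-type proportions
#'
#' @param breakdown Output of [response_type_breakdown()].
#' @return A ggplot object.
#' @export
plot_response_types <- function(breakdown) {
  ggplot2::ggplot(breakdown$types,
                  ggplot2::aes(x = .data$response_type, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proportion of productions") +
    ggplot2::theme_minimal()
}

#' Bar chart of the hop distribution
#'
#' Frequency of correct responses by shortest-path distance (hops) from the
#' stimulus, with path-less responses in the `"disconnected"` bin.
#'
#' @param breakdown Output of [response_type_breakdown()] with `hops`, or a
#'   tibble with columns `hop` and `prop`.
#' @return A ggplot object.
#' @export
plot_hop_distribution <- function(breakdown) {
  hops <- if (is.data.frame(breakdown)) breakdown else breakdown$hops
  if (is.null(hops)) stop("no hop table available", call. = FALSE)
  hops$hop <- factor(hops$hop, levels = hops$hop)
  ggplot2::ggplot(hops, ggplot2::aes(x = .data$hop, y = .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "hops from stimulus", y = "proportion of responses") +
    ggplot2::theme_minimal()
}
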