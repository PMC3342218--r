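#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Evaluation chart of a similarity trace
#'
#' Reproduces the evaluation-chart layout: percentage of evaluated
#' neighbours on the x axis, average semantic similarity on the y axis,
#' with the algorithm, optimal and random traces.
#'
#' @param object An `mll_trace`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mll_trace
#' @export
autoplot.mll_trace <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction * 100,
                                     y = .data$similarity,
                                     colour = .data$trace,
                                     linetype = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(algorithm = "#1f77b4",
                                            optimal = "#2ca02c",
                                            random = "grey40")) +
    ggplot2::scale_linetype_manual(values = c(algorithm = "solid",
                                              optimal = "dashed",
                                              random = "dotted")) +
    ggplot2::labs(x = "% of evaluated neighbours",
                  y = "average semantic similarity",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Draw a network layout
#'
#' @param object An `mll_layout`.
#' @param graph Optional `mll_graph` (or edge table); when supplied, edges
#'   are drawn as segments under the nodes.
#' @param node_colour Optional named vector or tibble (`node`, value)
#'   colouring the nodes, e.g. module labels.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot mll_layout
#' @export
autoplot.mll_layout <- function(object, graph = NULL, node_colour = NULL,
                                ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(graph)) {
    ed <- graph_edges(graph)
    seg <- tibble::tibble(
      x = df$x[match(ed$from, df$node)],
      y = df$y[match(ed$from, df$node)],
      xend = df$x[match(ed$to, df$node)],
      yend = df$y[match(ed$to, df$node)]
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.2, alpha = 0.6
    )
  }
  if (!is.null(node_colour)) {
    if (is.data.frame(node_colour)) {
      node_colour <- stats::setNames(node_colour[[2]], node_colour[[1]])
    }
    df$colour <- unname(node_colour[df$node])
    p <- p + ggplot2::geom_point(data = df,
                                 ggplot2::aes(colour = .data$colour),
                                 size = 1) +
      ggplot2::labs(colour = NULL)
  } else {
    p <- p + ggplot2::geom_point(size = 1)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' @method tidy mll_trace
#' @export
tidy.mll_trace <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = c("algorithm", "optimal", "random"),
                      names_to = "trace", values_to = "similarity")
}

#' @method glance mll_trace
#' @export
glance.mll_trace <- function(x, ...) {
  tibble::tibble(
    score = semantic_similarity_score(x),
    random_level = x$random[1],
    n_edges_evaluated = attr(x, "n_edges_evaluated"),
    n_excluded = attr(x, "n_excluded") %||% 0L
  )
}

#' @method tidy mll_eval
#' @export
tidy.mll_eval <- function(x, ...) x$scores

#' @method glance mll_eval
#' @export
glance.mll_eval <- function(x, ...) {
  tibble::tibble(mean_score = x$mean, sem = x$sem, n_runs = x$n,
                 single_run = x$single_run)
}
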