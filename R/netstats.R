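#' Edge density of an undirected simple graph
#'
#' `D = 2m / (n (n - 1))`, the fraction of possible node pairs that are
#' connected.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param n_edges Number of edges.
#' @return Density in `[0, 1]`.
#' @examples
#' net_density(426, 568) # a sparse two-hybrid screen, ~0.006
#' @export
net_density <- function(n_nodes, n_edges) {
  if (any(n_nodes < 2)) {
    stop("density is undefined for fewer than 2 nodes", call. = FALSE)
  }
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Mean node degree
#'
#' `MND = 2m / n`. The companion spread statistic reported by
#' [summarize_network()] is the standard deviation of the degree sequence.
#'
#' @param g An `mll_graph` or edge table.
#' @return Mean degree (dimensionless).
#' @export
mean_node_degree <- function(g) {
  g <- as_mll_graph(g)
  2 * nrow(g$edges) / length(g$nodes)
}

#' Topological summary of a network
#'
#' One row of summary statistics in the style of interaction-network
#' surveys: node and edge counts, density, mean node degree and its standard
#' deviation, and the mean local clustering coefficient. Degree-0/1 nodes
#' contribute a clustering coefficient of 0 to the mean, the convention
#' under which sparse screens show the expected low values.
#'
#' @param g An `mll_graph` or edge table.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1) for the degree standard deviation.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, `density`,
#'   `mean_degree`, `sd_degree`, `mean_cc`.
#' @examples
#' tri <- build_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' summarize_network(tri)
#' @export
summarize_network <- function(g, sd_type = c("population", "sample")) {
  g <- as_mll_graph(g)
  sd_type <- match.arg(sd_type)
  deg <- node_degrees(g)
  n <- length(deg)
  sd_deg <- if (sd_type == "sample") {
    stats::sd(deg)
  } else {
    sqrt(sum((deg - mean(deg))^2) / n)
  }
  tibble::tibble(
    n_nodes = n,
    n_edges = nrow(g$edges),
    density = net_density(n, nrow(g$edges)),
    mean_degree = mean_node_degree(g),
    sd_degree = if (n > 1) sd_deg else 0,
    mean_cc = mean(clustering_coefficients(g)$cc)
  )
}
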