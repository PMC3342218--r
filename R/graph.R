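#' Build an undirected interaction graph from an edge table
#'
#' Constructs the level-0 graph of the multilevel hierarchy from a two-column
#' edge table. Node identifiers are treated as opaque strings (gene symbols,
#' ORF names and numeric ids coexist in interaction files, so integer-looking
#' ids are not coerced). Duplicate edges (in either orientation) and
#' self-loops are dropped with a message rather than an error, because
#' published interaction files routinely contain both.
#'
#' @param edges A data frame whose first two columns are the edge endpoints,
#'   a two-column matrix, or a list of length-2 vectors.
#' @param level Hierarchy level of the graph; level 0 is the original
#'   network and forces all node weights to 1.
#' @param weight Optional named vector of positive integer node weights
#'   (the number of original nodes a metanode represents). Defaults to 1
#'   per node.
#'
#' @return An object of class `mll_graph`: a list with components
#'   `nodes` (sorted character vector), `edges` (tibble with columns
#'   `from`, `to`, canonically ordered so `from < to`), `weight`
#'   (named numeric) and `level` (integer).
#'
#' @examples
#' g <- build_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
#' g
#' @export
build_graph <- function(edges, level = 0L, weight = NULL) {
  ep <- as_edge_table(edges)
  if (nrow(ep) == 0L) {
    stop("empty edge list: a graph needs at least one edge", call. = FALSE)
  }
  loops <- ep$from == ep$to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    ep <- ep[!loops, , drop = FALSE]
  }
  if (nrow(ep) == 0L) {
    stop("empty edge list after removing self-loops", call. = FALSE)
  }
  # canonical orientation, then dedup
  swap <- ep$from > ep$to
  tmp <- ep$from[swap]
  ep$from[swap] <- ep$to[swap]
  ep$to[swap] <- tmp
  dup <- duplicated(paste(ep$from, ep$to, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) dropped")
    ep <- ep[!dup, , drop = FALSE]
  }
  nodes <- sort(unique(c(ep$from, ep$to)))
  if (is.null(weight)) {
    weight <- stats::setNames(rep(1, length(nodes)), nodes)
  } else {
    weight <- weight[nodes]
  }
  new_mll_graph(nodes, ep, weight, level)
}

# Normalise the accepted edge inputs to a character tibble(from, to).
as_edge_table <- function(edges) {
  if (inherits(edges, "mll_graph")) {
    return(edges$edges)
  }
  if (is.matrix(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    stopifnot(all(lengths(edges) == 2L))
    edges <- data.frame(
      from = vapply(edges, function(p) as.character(p[[1]]), character(1)),
      to = vapply(edges, function(p) as.character(p[[2]]), character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    stop("`edges` must have at least two columns", call. = FALSE)
  }
  tibble::tibble(
    from = as.character(edges[[1]]),
    to = as.character(edges[[2]])
  )
}

new_mll_graph <- function(nodes, edges, weight, level) {
  edges <- dplyr::arrange(tibble::as_tibble(edges[c("from", "to")]),
                          .data$from, .data$to)
  weight <- weight[nodes]
  stopifnot(
    !anyNA(weight), all(weight >= 1),
    all(edges$from %in% nodes), all(edges$to %in% nodes),
    all(edges$from < edges$to)
  )
  if (level == 0L && !all(weight == 1)) {
    stop("all node weights must be 1 at level 0", call. = FALSE)
  }
  structure(
    list(nodes = nodes, edges = edges, weight = weight,
         level = as.integer(level)),
    class = "mll_graph"
  )
}

#' @export
print.mll_graph <- function(x, ...) {
  cat(sprintf("<mll_graph> level %d: %d nodes, %d edges (total weight %g)\n",
              x$level, length(x$nodes), nrow(x$edges), sum(x$weight)))
  invisible(x)
}

#' Coerce to an mll_graph
#'
#' Data frames and matrices are passed through [build_graph()]; existing
#' `mll_graph` objects are returned unchanged.
#'
#' @param x An `mll_graph`, edge data frame, matrix or list of pairs.
#' @return An `mll_graph`.
#' @export
as_mll_graph <- function(x) {
  if (inherits(x, "mll_graph")) x else build_graph(x)
}

#' Node and edge tables of a graph
#'
#' @param g An `mll_graph`.
#' @return `graph_nodes()`: a tibble with columns `node`, `weight`,
#'   `degree`. `graph_edges()`: a tibble with columns `from`, `to`.
#' @export
graph_nodes <- function(g) {
  g <- as_mll_graph(g)
  tibble::tibble(node = g$nodes,
                 weight = unname(g$weight),
                 degree = unname(node_degrees(g)))
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(g) as_mll_graph(g)$edges

node_degrees <- function(g) {
  d <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes))
  stats::setNames(as.numeric(d), g$nodes)
}

adjacency_list <- function(g) {
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (nm in g$nodes) adj[[nm]] <- character(0)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$from[i]
    b <- g$edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

as_igraph <- function(g) {
  g <- as_mll_graph(g)
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Extract the largest connected component
#'
#' Interaction screens produce fragmented networks; layout and evaluation
#' operate on the largest connected component. Ties in component size are
#' broken deterministically by the component containing the
#' lexicographically smallest node id, so repeated runs agree.
#'
#' @param g An `mll_graph` or edge table.
#' @return The induced `mll_graph` on the largest component.
#' @export
largest_component <- function(g) {
  g <- as_mll_graph(g)
  comp <- igraph::components(as_igraph(g))
  member <- split(g$nodes, comp$membership[g$nodes])
  sizes <- vapply(member, length, integer(1))
  min_id <- vapply(member, min, character(1))
  keep <- member[[order(-sizes, min_id)[1]]]
  induced_subgraph_mll(g, keep)
}

induced_subgraph_mll <- function(g, keep) {
  ep <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, , drop = FALSE]
  new_mll_graph(sort(keep), ep, g$weight[sort(keep)], g$level)
}

#' Local clustering coefficients
#'
#' The clustering coefficient of a node is the number of edges connecting
#' its neighbours divided by the maximum possible number of such edges;
#' nodes of degree 0 or 1 have coefficient 0. Used both as a network summary
#' and to modulate forces in the clustering mode of the layout engine.
#'
#' @param g An `mll_graph` or edge table.
#' @param node Optional single node id; if given, the scalar CC of that node.
#' @return A tibble with columns `node`, `cc` (or a scalar when `node` is
#'   given).
#' @examples
#' tri <- build_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' clustering_coefficients(tri)
#' @export
clustering_coefficients <- function(g, node = NULL) {
  g <- as_mll_graph(g)
  ig <- as_igraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  names(cc) <- igraph::V(ig)$name
  cc <- cc[g$nodes]
  if (!is.null(node)) {
    if (!node %in% g$nodes) {
      stop("unknown node: ", node, call. = FALSE)
    }
    return(unname(cc[node]))
  }
  tibble::tibble(node = g$nodes, cc = unname(cc))
}
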