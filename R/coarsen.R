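#' Randomized weighted edge matching
#'
#' Selects a maximal independent set of edges for contraction. Nodes are
#' visited in a random order; each still-unmatched node is matched with the
#' unmatched neighbour that minimises the weighting score, so light nodes
#' (representing few original nodes) are absorbed first and metanode weights
#' stay balanced. Nodes left without an unmatched neighbour carry over to
#' the next level as singletons. Finding a maximum matching is NP-hard in
#' the weighted setting; this greedy pass settles for a maximal one.
#'
#' @param g An `mll_graph`.
#' @param weighting `"degree_modified"` scores a candidate neighbour `u` as
#'   `w(u) * (1 + deg(u))`, discouraging absorption of hubs in star-like
#'   networks; `"original"` uses the plain node weight `w(u)`.
#' @param seed Optional integer seed. When `NULL` the current RNG state is
#'   used, so a caller can drive a whole hierarchy from one seed.
#' @return An object of class `mll_matching`: list with `pairs` (tibble
#'   `a`, `b`) and `singletons` (character vector).
#' @export
match_nodes <- function(g, weighting = c("degree_modified", "original"),
                        seed = NULL) {
  g <- as_mll_graph(g)
  weighting <- match.arg(weighting)
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency_list(g)
  deg <- node_degrees(g)
  w <- g$weight
  score <- if (weighting == "original") w else w * (1 + deg)
  visit <- if (length(g$nodes) == 1L) g$nodes else sample(g$nodes)
  matched <- stats::setNames(rep(FALSE, length(g$nodes)), g$nodes)
  pa <- character(0)
  pb <- character(0)
  for (v in visit) {
    if (matched[[v]]) next
    cand <- adj[[v]]
    cand <- cand[!matched[cand]]
    if (length(cand) == 0L) next
    u <- cand[order(score[cand], cand)[1]]  # ties to smallest id
    matched[[v]] <- TRUE
    matched[[u]] <- TRUE
    pa <- c(pa, v)
    pb <- c(pb, u)
  }
  structure(
    list(pairs = tibble::tibble(a = pa, b = pb),
         singletons = g$nodes[!matched]),
    class = "mll_matching"
  )
}

#' @export
print.mll_matching <- function(x, ...) {
  cat(sprintf("<mll_matching> %d pair(s), %d singleton(s)\n",
              nrow(x$pairs), length(x$singletons)))
  invisible(x)
}

#' Contract a matching into the next coarser graph
#'
#' Each matched pair becomes a metanode whose weight is the sum of the
#' member weights; singletons carry over unchanged. Edges are projected onto
#' the metanodes: parallel projected edges collapse to one, and the edge
#' inside a contracted pair disappears.
#'
#' @param g An `mll_graph`.
#' @param m An `mll_matching` produced from `g`.
#' @return A list with `graph` (the contracted `mll_graph`, level
#'   incremented) and `parent_map` (named character vector: node of `g` ->
#'   node of the contracted graph).
#' @export
contract_graph <- function(g, m) {
  g <- as_mll_graph(g)
  validate_matching(g, m)
  lvl <- g$level + 1L
  parent <- stats::setNames(m$singletons, m$singletons)
  if (nrow(m$pairs) > 0L) {
    lo <- pmin(m$pairs$a, m$pairs$b)
    ord <- order(lo)
    nm <- sprintf("mn%d_%d", lvl, seq_len(nrow(m$pairs)))
    while (any(nm %in% m$singletons)) nm <- paste0(nm, "x")
    parent[m$pairs$a[ord]] <- nm
    parent[m$pairs$b[ord]] <- nm
  }
  w_new <- tapply(g$weight[names(parent)], parent, sum)
  nodes <- sort(unique(unname(parent)))
  ef <- unname(parent[g$edges$from])
  et <- unname(parent[g$edges$to])
  keep <- ef != et
  ep <- tibble::tibble(from = pmin(ef[keep], et[keep]),
                       to = pmax(ef[keep], et[keep]))
  ep <- ep[!duplicated(paste(ep$from, ep$to, sep = "\r")), , drop = FALSE]
  gg <- new_mll_graph(nodes, ep, stats::setNames(as.numeric(w_new),
                                                 names(w_new)), lvl)
  list(graph = gg, parent_map = parent)
}

validate_matching <- function(g, m) {
  if (!inherits(m, "mll_matching")) {
    stop("`m` must be an mll_matching", call. = FALSE)
  }
  seen <- c(m$pairs$a, m$pairs$b, m$singletons)
  if (anyDuplicated(seen) || !setequal(seen, g$nodes)) {
    stop("matching is not a partition of the graph's nodes", call. = FALSE)
  }
  if (nrow(m$pairs) > 0L) {
    key <- paste(pmin(m$pairs$a, m$pairs$b),
                 pmax(m$pairs$a, m$pairs$b), sep = "\r")
    ekey <- paste(g$edges$from, g$edges$to, sep = "\r")
    if (!all(key %in% ekey)) {
      stop("matching contains a pair that is not an edge", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build the full coarsening hierarchy
#'
#' Repeats [match_nodes()] and [contract_graph()] until at most two nodes
#' remain; for a connected input the terminal graph is exactly two nodes
#' joined by one edge. Node weight is conserved across levels: at every
#' level the weights sum to the number of original nodes.
#'
#' @param g A connected `mll_graph` (or edge table) with at least 2 nodes.
#'   Disconnected input is an error; extract the largest component first
#'   with [largest_component()].
#' @param weighting Matching score, see [match_nodes()].
#' @param seed Integer seed driving the visit order at every level.
#' @return An object of class `mll_hierarchy`: list with `levels` (list of
#'   `mll_graph` from level 0 up), `parent_maps` (list of named vectors,
#'   one per contraction), `weighting` and `seed`.
#' @examples
#' g <- build_graph(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")))
#' h <- build_hierarchy(g, seed = 1)
#' hierarchy_summary(h)
#' @export
build_hierarchy <- function(g, weighting = c("degree_modified", "original"),
                            seed = NULL) {
  g <- as_mll_graph(g)
  weighting <- match.arg(weighting)
  if (length(g$nodes) < 2L) {
    stop("hierarchy needs at least 2 nodes", call. = FALSE)
  }
  if (igraph::components(as_igraph(g))$no > 1L) {
    stop("graph is disconnected; extract the largest component first ",
         "(largest_component())", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  levels <- list(g)
  maps <- list()
  cur <- g
  while (length(cur$nodes) > 2L) {
    m <- match_nodes(cur, weighting)
    if (nrow(m$pairs) == 0L) break  # cannot occur on connected graphs
    res <- contract_graph(cur, m)
    cur <- res$graph
    levels[[length(levels) + 1L]] <- cur
    maps[[length(maps) + 1L]] <- res$parent_map
  }
  structure(
    list(levels = levels, parent_maps = maps,
         weighting = weighting, seed = seed),
    class = "mll_hierarchy"
  )
}

#' @export
print.mll_hierarchy <- function(x, ...) {
  cat(sprintf("<mll_hierarchy> %d level(s), %d -> %d nodes\n",
              length(x$levels), length(x$levels[[1]]$nodes),
              length(x$levels[[length(x$levels)]]$nodes)))
  invisible(x)
}

#' Per-level summary of a hierarchy
#'
#' @param h An `mll_hierarchy`.
#' @return A tibble with columns `level`, `n_nodes`, `n_edges`,
#'   `total_weight`.
#' @export
hierarchy_summary <- function(h) {
  stopifnot(inherits(h, "mll_hierarchy"))
  tibble::tibble(
    level = vapply(h$levels, function(g) g$level, integer(1)),
    n_nodes = vapply(h$levels, function(g) length(g$nodes), integer(1)),
    n_edges = vapply(h$levels, function(g) nrow(g$edges), integer(1)),
    total_weight = vapply(h$levels, function(g) sum(g$weight), numeric(1))
  )
}
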