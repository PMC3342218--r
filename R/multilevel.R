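#' Automatic downscaling of an over-wide layout
#'
#' Very large graphs with many coarsening levels can blow the layout up
#' until inter-node arithmetic loses precision; when the bounding box
#' exceeds `width_limit` in either direction, all coordinates and the
#' natural spring length are multiplied by `width_limit / max(extent)`, a
#' similarity transform that preserves all relative distances. The spring
#' length is floored at `1e-3` layout units to guard against coordinate
#' underflow.
#'
#' @param layout An `mll_layout` (or data frame `node`, `x`, `y`).
#' @param params An [force_params()] object (its `width_limit` is used and
#'   its `spring_length` possibly rescaled).
#' @return A list with the (possibly rescaled) `layout` and `params`.
#' @export
auto_downscale <- function(layout, params) {
  ext <- max(diff(range(layout$x)), diff(range(layout$y)))
  if (is.finite(ext) && ext > params$width_limit) {
    s <- params$width_limit / ext
    layout$x <- layout$x * s
    layout$y <- layout$y * s
    params$spring_length <- max(params$spring_length * s, 1e-3)
  }
  list(layout = layout, params = params)
}

#' Multilevel force-directed layout
#'
#' The full two-phase algorithm. Phase 1 coarsens the graph into a
#' hierarchy `G_0 .. G_L` by randomized weighted matching
#' ([build_hierarchy()]); for a connected input `G_L` is two nodes and one
#' edge. Phase 2 uncoarsens from the top: the nodes of `G_L` are placed
#' uniformly at random on the canvas, and at each finer level the members
#' of a metanode start at the metanode's refined position (pass-through
#' singletons inherit their own), after which [refine_level()] relaxes the
#' level with node-weighted forces. Clustering coefficients are computed
#' once on `G_0` and projected onto metanodes as the weight-weighted mean
#' of their members' values. [auto_downscale()] runs between levels.
#'
#' @param g A connected `mll_graph` or edge table with >= 2 nodes (extract
#'   the largest component of fragmented networks first).
#' @param params An [force_params()] object.
#' @param seed Integer seed; one seeded generator drives matching order,
#'   canvas placement and jitter, so a fixed seed reproduces the layout
#'   bit for bit.
#' @return An `mll_layout` tibble (`node`, `x`, `y`) for `G_0`, with
#'   attributes `seed`, `hierarchy_depth`, `iterations` (per level, from
#'   `G_L` down) and `spring_length`.
#' @examples
#' g <- build_graph(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C")))
#' multilevel_layout(g, seed = 1)
#' @export
multilevel_layout <- function(g, params = force_params(), seed = NULL) {
  g <- as_mll_graph(g)
  if (length(g$nodes) < 2L) {
    stop("layout needs at least 2 nodes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  h <- build_hierarchy(g, params$weighting)
  ccs <- propagate_cc(h, params)
  n_levels <- length(h$levels)
  top <- h$levels[[n_levels]]
  cur <- random_layout(top, params$spring_length)
  cur_params <- params
  iters <- integer(0)
  for (li in rev(seq_len(n_levels))) {
    gi <- h$levels[[li]]
    if (li < n_levels) {
      parent <- h$parent_maps[[li]]
      idx <- match(unname(parent[gi$nodes]), cur$node)
      cur <- tibble::tibble(node = gi$nodes,
                            x = cur$x[idx], y = cur$y[idx])
    }
    cur <- refine_level(gi, cur, cur_params, cc = ccs[[li]])
    iters <- c(iters, attr(cur, "iterations"))
    ds <- auto_downscale(cur, cur_params)
    cur <- ds$layout
    cur_params <- ds$params
  }
  out <- new_mll_layout(cur, spring_length = cur_params$spring_length,
                        level = 0L, seed = seed, iterations = iters)
  attr(out, "hierarchy_depth") <- n_levels - 1L
  out
}

propagate_cc <- function(h, params) {
  n_levels <- length(h$levels)
  ccs <- vector("list", n_levels)
  g0 <- h$levels[[1]]
  cc0 <- if (params$clustering) {
    tb <- clustering_coefficients(g0)
    stats::setNames(tb$cc, tb$node)
  } else {
    stats::setNames(rep(0, length(g0$nodes)), g0$nodes)
  }
  ccs[[1]] <- cc0
  if (n_levels > 1) {
    for (li in seq_len(n_levels - 1)) {
      child_g <- h$levels[[li]]
      parent <- h$parent_maps[[li]]
      wsum <- tapply(child_g$weight[names(parent)], parent, sum)
      csum <- tapply(child_g$weight[names(parent)] *
                       ccs[[li]][names(parent)], parent, sum)
      ccs[[li + 1]] <- stats::setNames(as.numeric(csum / wsum), names(wsum))
    }
  }
  ccs
}

#' Single-level force-directed baseline
#'
#' A plain force-directed layout — random initial placement of all nodes
#' followed by one [refine_level()] pass, with no hierarchy and (by
#' default) no clustering modulation. This is the single-level reduction
#' of the multilevel method and serves as the in-package reference
#' baseline when comparing layout quality.
#'
#' @inheritParams multilevel_layout
#' @return An `mll_layout`.
#' @export
fdl_layout <- function(g, params = force_params(clustering = FALSE),
                       seed = NULL) {
  g <- as_mll_graph(g)
  if (!is.null(seed)) set.seed(seed)
  init <- random_layout(g, params$spring_length)
  out <- refine_level(g, init, params)
  attr(out, "seed") <- seed
  attr(out, "hierarchy_depth") <- 0L
  out
}

#' Repeated layouts over consecutive seeds
#'
#' Layout algorithms with random initialisation are assessed over several
#' runs; this produces `n_runs` independent layouts with seeds
#' `base_seed, base_seed + 1, ...` for downstream score averaging and SEM.
#'
#' @param g Graph, see [multilevel_layout()].
#' @param params An [force_params()] object.
#' @param n_runs Number of layouts (>= 1).
#' @param base_seed Seed of the first run.
#' @param method `"multilevel"` (default), `"fdl"` or `"random"`.
#' @return A list of `mll_layout` objects.
#' @export
repeat_layout <- function(g, params = force_params(), n_runs = 10,
                          base_seed = 1, method = c("multilevel", "fdl",
                                                    "random")) {
  stopifnot(n_runs >= 1)
  method <- match.arg(method)
  g <- as_mll_graph(g)
  fun <- switch(method,
    multilevel = function(s) multilevel_layout(g, params, seed = s),
    fdl = function(s) fdl_layout(g, params, seed = s),
    random = function(s) random_layout(g, params$spring_length, seed = s)
  )
  lapply(base_seed + seq_len(n_runs) - 1, fun)
}
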