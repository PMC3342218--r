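#' Force-model parameters
#'
#' Bundles the tunables of the node-weighted Fruchterman–Reingold engine.
#' The natural spring length `spring_length` (k) sets the global scale of
#' the layout; `repulsion_multiplier` (C) scales the repulsive force — a
#' higher value pushes nodes further apart; `tolerance` controls
#' convergence — a sweep stops the refinement once no node moved more than
#' `tolerance * k`. The clustering option modulates forces by local
#' clustering coefficients to separate dense modules: attraction between
#' adjacent nodes is multiplied by `1 + cc_alpha * mean(CC)` and repulsion
#' between non-adjacent nodes by `1 + cc_beta * max(CC)`.
#'
#' @param spring_length Natural spring length k, layout units (> 0).
#' @param repulsion_multiplier Repulsion constant C (> 0).
#' @param tolerance Convergence threshold as a fraction of k (> 0).
#' @param cc_alpha,cc_beta Clustering-coefficient gains for attraction and
#'   repulsion (used only when `clustering = TRUE`).
#' @param clustering Toggle the clustering-coefficient modulation
#'   (on by default).
#' @param cutoff_factor Repulsion is truncated beyond
#'   `cutoff_factor * k * sqrt(w)` of the node being moved; this truncation
#'   is what makes the spatial index pay off. The `"brute"` backend applies
#'   no cutoff.
#' @param max_iterations Sweep budget per hierarchy level.
#' @param cooling_factor Temperature decay per sweep, in (0, 1).
#' @param weighting Matching score used during coarsening, see
#'   [match_nodes()].
#' @param spatial_index Index backend, see [build_spatial_index()].
#' @param width_limit Bounding-box extent beyond which the layout is
#'   automatically downscaled, see [auto_downscale()].
#' @param dense_threshold Below this node count forces are computed with a
#'   full masked distance matrix (identical results to per-node index
#'   queries, measurably faster in R); above it the engine loops over
#'   per-node range queries.
#' @return An object of class `mll_force_params`.
#' @export
force_params <- function(spring_length = 100,
                         repulsion_multiplier = 0.2,
                         tolerance = 0.01,
                         cc_alpha = 1,
                         cc_beta = 1,
                         clustering = TRUE,
                         cutoff_factor = 3,
                         max_iterations = 300L,
                         cooling_factor = 0.95,
                         weighting = c("degree_modified", "original"),
                         spatial_index = c("grid", "mtree", "brute"),
                         width_limit = 1e6,
                         dense_threshold = 2000L) {
  stopifnot(spring_length > 0, repulsion_multiplier > 0, tolerance > 0,
            cc_alpha >= 0, cc_beta >= 0, cutoff_factor > 0,
            max_iterations >= 1, cooling_factor > 0, cooling_factor < 1,
            width_limit > 0)
  structure(
    list(spring_length = spring_length,
         repulsion_multiplier = repulsion_multiplier,
         tolerance = tolerance,
         cc_alpha = cc_alpha, cc_beta = cc_beta,
         clustering = isTRUE(clustering),
         cutoff_factor = cutoff_factor,
         max_iterations = as.integer(max_iterations),
         cooling_factor = cooling_factor,
         weighting = match.arg(weighting),
         spatial_index = match.arg(spatial_index),
         width_limit = width_limit,
         dense_threshold = as.integer(dense_threshold)),
    class = "mll_force_params"
  )
}

#' @export
print.mll_force_params <- function(x, ...) {
  cat("<mll_force_params>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Elementary force laws
#'
#' The classic Fruchterman–Reingold pair forces, with the node-weight and
#' repulsion-multiplier extensions: repulsion `C * w * k^2 / d` (directed
#' away from the other node, whose weight is `w`) and attraction `d^2 / k`
#' (toward the neighbour; node weights do not enter the attraction).
#' Both are vectorised.
#'
#' @param d Pair distance (> 0 for repulsion).
#' @param k Natural spring length.
#' @param C Repulsion multiplier.
#' @param w Weight of the repelling node.
#' @return Force magnitude(s).
#' @export
repulsive_force <- function(d, k, C = 1, w = 1) {
  C * w * k^2 / d
}

#' @rdname repulsive_force
#' @export
attractive_force <- function(d, k) {
  d^2 / k
}

#' Clustering-coefficient force modulation
#'
#' Emphasises attraction between connected high-CC nodes and repulsion
#' between nodes of different dense clusters. For an adjacent pair the
#' attractive magnitude is multiplied by `1 + cc_alpha * (cc_u + cc_v)/2`;
#' for a non-adjacent pair the repulsive magnitude is multiplied by
#' `1 + cc_beta * max(cc_u, cc_v)`. With both gains 0 the forces are
#' returned unchanged (plain multilevel mode).
#'
#' @param f_attr,f_rep Unmodulated attractive and repulsive magnitudes.
#' @param cc_u,cc_v Clustering coefficients of the two nodes, in `[0, 1]`.
#' @param cc_alpha,cc_beta Gains.
#' @param adjacent Is the pair connected by an edge?
#' @return A list with elements `attr` and `rep`.
#' @export
cc_modulate <- function(f_attr, f_rep, cc_u, cc_v,
                        cc_alpha = 1, cc_beta = 1, adjacent = TRUE) {
  if (adjacent) {
    list(attr = f_attr * (1 + cc_alpha * (cc_u + cc_v) / 2), rep = f_rep)
  } else {
    list(attr = f_attr, rep = f_rep * (1 + cc_beta * pmax(cc_u, cc_v)))
  }
}

new_mll_layout <- function(positions, spring_length, level = 0L,
                           seed = NULL, iterations = NULL,
                           converged = NA) {
  structure(
    tibble::as_tibble(positions[c("node", "x", "y")]),
    spring_length = spring_length,
    level = level,
    seed = seed,
    iterations = iterations,
    converged = converged,
    class = c("mll_layout", class(tibble::tibble()))
  )
}

#' Uniformly random layout
#'
#' Places every node independently and uniformly in a square canvas of side
#' `10 * k` centred at the origin — the initial placement of the coarsest
#' graph, and the null reference layout in evaluations.
#'
#' @param g An `mll_graph` or edge table.
#' @param spring_length Natural spring length k (sets the canvas side).
#' @param seed Optional integer seed.
#' @return An `mll_layout` tibble with columns `node`, `x`, `y`.
#' @export
random_layout <- function(g, spring_length = 100, seed = NULL) {
  g <- as_mll_graph(g)
  if (!is.null(seed)) set.seed(seed)
  half <- 5 * spring_length
  n <- length(g$nodes)
  new_mll_layout(
    tibble::tibble(node = g$nodes,
                   x = stats::runif(n, -half, half),
                   y = stats::runif(n, -half, half)),
    spring_length = spring_length, seed = seed
  )
}

#' Force-directed refinement of one hierarchy level
#'
#' Runs node-weighted Fruchterman–Reingold sweeps from an initial layout.
#' Each sweep computes, from a snapshot of the positions, every node's net
#' displacement — repulsion summed over the nodes within the cutoff radius
#' (fetched through the spatial index; no cutoff for the `"brute"`
#' backend), attraction over incident edges, optionally CC-modulated — then
#' caps each displacement at the current temperature and applies them all.
#' The temperature starts at one tenth of the initial bounding-box diagonal
#' and is multiplied by `cooling_factor` after every sweep; refinement
#' stops when the largest applied displacement falls below
#' `tolerance * k` or after `max_iterations` sweeps (the latter logs a
#' warning rather than failing).
#'
#' Coincident nodes — the normal state right after uncoarsening, when the
#' members of a metanode start at its position — are separated once at
#' entry by a deterministic jitter of `1e-4 * k` in a seeded random
#' direction.
#'
#' @param g The `mll_graph` being laid out.
#' @param initial An `mll_layout` (or data frame `node`, `x`, `y`)
#'   covering all nodes of `g`.
#' @param params An [force_params()] object.
#' @param cc Optional clustering coefficients to modulate forces with: a
#'   tibble `node`, `cc` or named vector. During multilevel refinement
#'   these are the level-0 values projected onto metanodes. If `NULL` and
#'   clustering is on, they are computed from `g`.
#' @param seed Optional integer seed (jitter directions only; sweeps are
#'   deterministic given the start).
#' @return An `mll_layout` with attributes `iterations` and `converged`.
#' @export
refine_level <- function(g, initial, params = force_params(), cc = NULL,
                         seed = NULL) {
  g <- as_mll_graph(g)
  if (!is.null(seed)) set.seed(seed)
  pos <- layout_matrix(initial, g$nodes)
  n <- nrow(pos)
  k <- params$spring_length
  C <- params$repulsion_multiplier
  ccv <- resolve_cc(g, cc, params)
  alpha <- if (params$clustering) params$cc_alpha else 0
  beta <- if (params$clustering) params$cc_beta else 0
  w <- unname(g$weight)

  temp <- 0.1 * bbox_diagonal(pos)
  if (temp == 0) temp <- k
  pos <- jitter_coincident(pos, k)

  cutoff <- if (params$spatial_index == "brute") {
    rep(Inf, n)
  } else {
    params$cutoff_factor * k * sqrt(w)
  }
  dense <- n <= params$dense_threshold
  if (dense) {
    A <- adjacency_matrix_mll(g)
    attmod <- 1 + alpha * outer(ccv, ccv, "+") / 2
    repmod <- ifelse(A, 1, 1 + beta * outer(ccv, ccv, pmax))
    diag(repmod) <- 0  # no self-repulsion
    Wj <- matrix(w, n, n, byrow = TRUE)
  } else {
    adj_idx <- adjacency_index(g)
  }

  iter <- 0L
  converged <- FALSE
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    disp <- if (dense) {
      sweep_dense(pos, A, attmod, repmod, Wj, k, C, cutoff)
    } else {
      sweep_indexed(pos, adj_idx, ccv, w, k, C, alpha, beta, cutoff,
                    params$spatial_index)
    }
    len <- sqrt(disp[, 1]^2 + disp[, 2]^2)
    scale <- ifelse(len > temp, temp / len, 1)
    pos <- pos + disp * scale
    moved <- pmin(len, temp)
    temp <- temp * params$cooling_factor
    if (max(moved) < params$tolerance * k) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("refinement did not converge within max_iterations (",
            params$max_iterations, ")", call. = FALSE)
  }
  new_mll_layout(
    tibble::tibble(node = rownames(pos), x = pos[, 1], y = pos[, 2]),
    spring_length = k, level = g$level, seed = seed,
    iterations = iter, converged = converged
  )
}

# One Jacobi-style sweep over all nodes, full masked distance matrix.
sweep_dense <- function(pos, A, attmod, repmod, Wj, k, C, cutoff) {
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  d <- sqrt(dx * dx + dy * dy)
  safe <- pmax(d, 1e-12)
  mask <- (d <= cutoff) * repmod  # cutoff[i] recycles down rows: d[i,j] <= cutoff[i]
  rep_coef <- mask * repulsive_force(safe, k, C, Wj) / safe
  att_coef <- A * attmod * attractive_force(d, k) / safe
  cbind(rowSums(rep_coef * dx) - rowSums(att_coef * dx),
        rowSums(rep_coef * dy) - rowSums(att_coef * dy))
}

# Same sweep via per-node range queries against a freshly built index.
sweep_indexed <- function(pos, adj_idx, ccv, w, k, C, alpha, beta, cutoff,
                          backend) {
  n <- nrow(pos)
  ix <- build_spatial_index(pos, backend = backend)
  disp <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    nb <- range_query_idx(ix, pos[i, ], cutoff[i])
    nb <- nb[nb != i]
    if (length(nb) > 0) {
      dx <- pos[i, 1] - pos[nb, 1]
      dy <- pos[i, 2] - pos[nb, 2]
      d <- pmax(sqrt(dx * dx + dy * dy), 1e-12)
      mod <- rep(1, length(nb))
      nonadj <- !(nb %in% adj_idx[[i]])
      mod[nonadj] <- 1 + beta * pmax(ccv[i], ccv[nb[nonadj]])
      coef <- mod * repulsive_force(d, k, C, w[nb]) / d
      disp[i, ] <- c(sum(coef * dx), sum(coef * dy))
    }
    ni <- adj_idx[[i]]
    if (length(ni) > 0) {
      dx <- pos[i, 1] - pos[ni, 1]
      dy <- pos[i, 2] - pos[ni, 2]
      d <- sqrt(dx * dx + dy * dy)
      safe <- pmax(d, 1e-12)
      amod <- 1 + alpha * (ccv[i] + ccv[ni]) / 2
      coef <- amod * attractive_force(d, k) / safe
      disp[i, ] <- disp[i, ] - c(sum(coef * dx), sum(coef * dy))
    }
  }
  disp
}

layout_matrix <- function(layout, nodes) {
  stopifnot(is.data.frame(layout), all(c("node", "x", "y") %in% names(layout)))
  if (!all(nodes %in% layout$node)) {
    stop("initial layout does not cover all graph nodes", call. = FALSE)
  }
  m <- cbind(x = layout$x, y = layout$y)[match(nodes, layout$node), ,
                                         drop = FALSE]
  rownames(m) <- nodes
  if (!all(is.finite(m))) stop("non-finite layout coordinate", call. = FALSE)
  m
}

resolve_cc <- function(g, cc, params) {
  if (is.null(cc)) {
    if (params$clustering) {
      tb <- clustering_coefficients(g)
      cc <- stats::setNames(tb$cc, tb$node)
    } else {
      cc <- stats::setNames(rep(0, length(g$nodes)), g$nodes)
    }
  } else if (is.data.frame(cc)) {
    cc <- stats::setNames(cc$cc, cc$node)
  }
  unname(cc[g$nodes])
}

bbox_diagonal <- function(pos) {
  sqrt(diff(range(pos[, 1]))^2 + diff(range(pos[, 2]))^2)
}

jitter_coincident <- function(pos, k) {
  key <- paste(pos[, 1], pos[, 2], sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    ang <- stats::runif(length(dup), 0, 2 * pi)
    pos[dup, 1] <- pos[dup, 1] + 1e-4 * k * cos(ang)
    pos[dup, 2] <- pos[dup, 2] + 1e-4 * k * sin(ang)
  }
  pos
}

adjacency_matrix_mll <- function(g) {
  n <- length(g$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  fi <- match(g$edges$from, g$nodes)
  ti <- match(g$edges$to, g$nodes)
  A[cbind(fi, ti)] <- TRUE
  A[cbind(ti, fi)] <- TRUE
  A
}

adjacency_index <- function(g) {
  adj <- adjacency_list(g)
  lapply(g$nodes, function(v) match(adj[[v]], g$nodes))
}
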