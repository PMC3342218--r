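# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# clustering coefficient by exhaustive neighbour-pair scan
oracle_cc <- function(edges, v) {
  ek <- unique(rbind(as.matrix(edges[, 1:2]),
                     as.matrix(edges[, 2:1])))
  nb <- unique(ek[ek[, 1] == v, 2])
  d <- length(nb)
  if (d <= 1) return(0)
  t <- 0
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      if (any(ek[, 1] == nb[i] & ek[, 2] == nb[j])) t <- t + 1
    }
  }
  2 * t / (d * (d - 1))
}

# connected components by BFS over an edge table
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges[[1]], edges[[2]])))
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (s in nodes) {
    if (!is.na(comp[[s]])) next
    cid <- cid + 1L
    queue <- s
    comp[[s]] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v])
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  split(nodes, comp)
}

# quotient graph of a contraction, by direct set construction
oracle_quotient <- function(edges, parent) {
  pf <- unname(parent[edges[[1]]])
  pt <- unname(parent[edges[[2]]])
  keep <- pf != pt
  key <- unique(paste(pmin(pf[keep], pt[keep]),
                      pmax(pf[keep], pt[keep]), sep = "|"))
  sort(key)
}

# one textbook Fruchterman-Reingold sweep (plus C multiplier), double loop
oracle_fr_sweep <- function(pos, edge_idx, k, C, temp) {
  n <- nrow(pos)
  new <- pos
  for (i in seq_len(n)) {
    fr <- c(0, 0)
    for (j in seq_len(n)) {
      if (j == i) next
      delta <- pos[i, ] - pos[j, ]
      d <- max(sqrt(sum(delta^2)), 1e-12)
      fr <- fr + delta / d * (C * k^2 / d)
    }
    fa <- c(0, 0)
    for (e in seq_len(nrow(edge_idx))) {
      other <- if (edge_idx[e, 1] == i) edge_idx[e, 2]
               else if (edge_idx[e, 2] == i) edge_idx[e, 1]
               else next
      delta <- pos[i, ] - pos[other, ]
      d <- max(sqrt(sum(delta^2)), 1e-12)
      fa <- fa - delta / d * (d^2 / k)
    }
    disp <- fr + fa
    len <- sqrt(sum(disp^2))
    if (len > temp) disp <- disp / len * temp
    new[i, ] <- pos[i, ] + disp
  }
  new
}

# exhaustive range scan
oracle_range <- function(points, q, r) {
  d <- sqrt((points[, 1] - q[1])^2 + (points[, 2] - q[2])^2)
  sort(rownames(points)[d <= r])
}

# connected Erdos-Renyi graph via igraph (retry until connected)
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    ig <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(ig)) break
  }
  el <- igraph::as_edgelist(ig)
  build_graph(data.frame(from = sprintf("n%02d", el[, 1]),
                         to = sprintf("n%02d", el[, 2])))
}
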