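test_that("match_nodes: forced, triangle and path cases", {
  e <- build_graph(list(c("A", "B")))
  m <- match_nodes(e, seed = 99)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$singletons, 0)

  tri <- build_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  for (seed in 1:10) {
    m <- match_nodes(tri, seed = seed)
    expect_equal(nrow(m$pairs), 1)
    expect_length(m$singletons, 1)
  }

  p4 <- build_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
  for (seed in 1:20) {
    m <- match_nodes(p4, seed = seed)
    expect_true(nrow(m$pairs) %in% c(1, 2))
    # maximality: no edge joins two singletons
    s <- m$singletons
    joins <- p4$edges$from %in% s & p4$edges$to %in% s
    expect_false(any(joins))
  }
})

test_that("matching prefers the smallest weighting score, ties by node id", {
  # star with pre-weighted neighbours: original weighting picks the
  # lightest leaf; degree-modified penalises the high-degree neighbour
  g <- structure(list(
    nodes = c("h", "l1", "l2"),
    edges = tibble::tibble(from = c("h", "h", "l1"),
                           to = c("l1", "l2", "l2")),
    weight = c(h = 1, l1 = 3, l2 = 1),
    level = 1L
  ), class = "mll_graph")
  set.seed(1)
  # force visiting order by trying many seeds; whenever "h" is matched its
  # partner must be l2 (weight 1 < 3) under both weightings
  for (seed in 1:10) {
    for (wt in c("original", "degree_modified")) {
      m <- match_nodes(g, weighting = wt, seed = seed)
      row <- m$pairs[m$pairs$a == "h", ]
      if (nrow(row) == 1) expect_equal(row$b, "l2")
    }
  }
})

test_that("contract merges pairs into weighted metanodes", {
  e <- build_graph(list(c("A", "B")))
  m <- match_nodes(e, seed = 1)
  res <- contract_graph(e, m)
  expect_equal(length(res$graph$nodes), 1)
  expect_equal(nrow(res$graph$edges), 0)
  expect_equal(unname(res$graph$weight), 2)
  expect_equal(res$graph$level, 1L)

  g <- fig1_graph()
  res <- contract_graph(g, fig1_matching(g))
  expect_equal(length(res$graph$nodes), 5)
  expect_equal(sum(res$graph$weight), 8)
})

test_that("contracted edge set equals the brute-force quotient graph", {
  for (seed in 1:5) {
    g <- random_connected_graph(20, 0.2, seed = seed + 100)
    m <- match_nodes(g, seed = seed)
    res <- contract_graph(g, m)
    got <- sort(paste(res$graph$edges$from, res$graph$edges$to, sep = "|"))
    expect_equal(got, oracle_quotient(g$edges, res$parent_map))
  }
})

test_that("contract rejects invalid matchings", {
  g <- fig1_graph()
  bad <- structure(list(pairs = tibble::tibble(a = "N1", b = "N8"),
                        singletons = setdiff(g$nodes, c("N1", "N8"))),
                   class = "mll_matching")
  expect_error(contract_graph(g, bad), "not an edge")
  bad2 <- structure(list(pairs = tibble::tibble(a = "N1", b = "N2"),
                         singletons = g$nodes),
                    class = "mll_matching")
  expect_error(contract_graph(g, bad2), "partition")
})

test_that("build_hierarchy terminates at two nodes and one edge", {
  e <- build_graph(list(c("A", "B")))
  h <- build_hierarchy(e, seed = 1)
  expect_length(h$levels, 1)

  h <- build_hierarchy(fig1_graph(), seed = 3)
  top <- h$levels[[length(h$levels)]]
  expect_equal(length(top$nodes), 2)
  expect_equal(nrow(top$edges), 1)

  two <- build_graph(data.frame(u = c("a", "x"), v = c("b", "y")))
  expect_error(build_hierarchy(two), "disconnected")
})

test_that("hierarchy invariants hold across random connected graphs", {
  for (seed in 1:20) {
    n <- sample(10:60, 1)
    g <- random_connected_graph(n, min(1, 2.5 / n + 0.1), seed = seed)
    h <- build_hierarchy(g, seed = seed,
                         weighting = if (seed %% 2) "degree_modified"
                                     else "original")
    sizes <- vapply(h$levels, function(x) length(x$nodes), integer(1))
    # strict decrease and halving bound
    expect_true(all(diff(sizes) < 0))
    expect_true(all(sizes[-1] >= ceiling(sizes[-length(sizes)] / 2)))
    # weight conservation at every level
    for (lv in h$levels) {
      expect_equal(sum(lv$weight), length(g$nodes))
      expect_true(all(lv$weight >= 1))
    }
    # terminal state
    expect_lte(sizes[length(sizes)], 2)
    # parent maps total and surjective
    for (i in seq_along(h$parent_maps)) {
      pm <- h$parent_maps[[i]]
      expect_setequal(names(pm), h$levels[[i]]$nodes)
      expect_setequal(unique(unname(pm)), h$levels[[i + 1]]$nodes)
    }
  }
})

test_that("hierarchies are bit-reproducible under a fixed seed", {
  g <- random_connected_graph(30, 0.15, seed = 55)
  h1 <- build_hierarchy(g, seed = 9)
  h2 <- build_hierarchy(g, seed = 9)
  expect_identical(hierarchy_summary(h1), hierarchy_summary(h2))
  expect_identical(h1$parent_maps, h2$parent_maps)
})
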