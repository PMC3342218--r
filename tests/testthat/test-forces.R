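test_that("pair force laws are the analytic formulas", {
  k <- 100
  expect_equal(repulsive_force(k, k, C = 1, w = 1), k)
  expect_equal(repulsive_force(100, 100, C = 0.2, w = 1), 20)
  expect_equal(attractive_force(k, k), k)
  expect_equal(attractive_force(0, k), 0)

  set.seed(1)
  for (i in 1:20) {
    d <- runif(1, 1, 500); kk <- runif(1, 10, 300); C <- runif(1, 0.05, 2)
    w <- runif(1, 1, 50)
    expect_equal(repulsive_force(d, kk, C, 2 * w),
                 2 * repulsive_force(d, kk, C, w))
  }
})

test_that("cc modulation scales the right force and vanishes when off", {
  out <- cc_modulate(10, 7, 0, 0, cc_alpha = 3, cc_beta = 5,
                     adjacent = TRUE)
  expect_equal(out, list(attr = 10, rep = 7))
  out <- cc_modulate(10, 7, 0.8, 0.4, cc_alpha = 0, cc_beta = 0,
                     adjacent = FALSE)
  expect_equal(out, list(attr = 10, rep = 7))
  out <- cc_modulate(10, 7, 1, 1, cc_alpha = 1, adjacent = TRUE)
  expect_equal(out$attr, 20)  # attraction doubled at full CC, gain 1
  expect_equal(out$rep, 7)
  out <- cc_modulate(10, 7, 0.2, 0.6, cc_beta = 1, adjacent = FALSE)
  expect_equal(out$rep, 7 * 1.6)  # max(cc) drives the repulsion boost
})

test_that("one sweep equals the textbook FR sweep at machine precision", {
  set.seed(42)
  g <- random_connected_graph(15, 0.3, seed = 42)
  n <- length(g$nodes)
  init <- data.frame(node = g$nodes,
                     x = runif(n, -100, 100), y = runif(n, -100, 100))
  p <- force_params(clustering = FALSE, spatial_index = "brute",
                    max_iterations = 1L, tolerance = 1e-9)
  got <- suppressWarnings(refine_level(g, init, p))
  pos0 <- cbind(init$x, init$y)
  rownames(pos0) <- init$node
  eidx <- cbind(match(g$edges$from, g$nodes), match(g$edges$to, g$nodes))
  temp <- 0.1 * sqrt(diff(range(pos0[, 1]))^2 + diff(range(pos0[, 2]))^2)
  want <- oracle_fr_sweep(pos0, eidx, p$spring_length,
                          p$repulsion_multiplier, temp)
  expect_lt(max(abs(cbind(got$x, got$y) - want[got$node, ])), 1e-9)
})

test_that("an isolated edge relaxes to the closed-form equilibrium", {
  g <- build_graph(list(c("A", "B")))
  for (k in c(50, 100)) {
    for (C in c(0.1, 0.2, 1)) {
      p <- force_params(spring_length = k, repulsion_multiplier = C,
                        clustering = FALSE)
      ly <- refine_level(g, random_layout(g, k, seed = 5), p, seed = 5)
      d <- sqrt(diff(ly$x)^2 + diff(ly$y)^2)
      expect_lt(abs(d - k * C^(1 / 3)) / (k * C^(1 / 3)), 0.05)
    }
  }
})

test_that("disconnected nodes only repel each other", {
  g <- structure(list(
    nodes = c("A", "B"),
    edges = tibble::tibble(from = character(), to = character()),
    weight = c(A = 1, B = 1), level = 0L
  ), class = "mll_graph")
  init <- data.frame(node = c("A", "B"), x = c(0, 30), y = c(0, 0))
  ly <- suppressWarnings(
    refine_level(g, init, force_params(spatial_index = "brute",
                                       max_iterations = 50L)))
  expect_gte(sqrt(diff(ly$x)^2 + diff(ly$y)^2), 30)
})

test_that("a 4-cycle relaxes to a near-rhombus", {
  g <- build_graph(data.frame(a = c("A", "B", "C", "D"),
                              b = c("B", "C", "D", "A")))
  ly <- refine_level(g, random_layout(g, 100, seed = 8),
                     force_params(clustering = FALSE), seed = 8)
  pos <- cbind(ly$x, ly$y)
  rownames(pos) <- ly$node
  el <- graph_edges(g)
  lens <- sqrt(rowSums((pos[el$from, ] - pos[el$to, ])^2))
  expect_lt(max(lens) / min(lens), 1.1)  # all edge lengths within 10%
})

test_that("refinement is translation-equivariant", {
  g <- random_connected_graph(12, 0.3, seed = 21)
  init <- random_layout(g, 100, seed = 2)
  p <- force_params(max_iterations = 8L)
  a <- suppressWarnings(refine_level(g, init, p, seed = 3))
  shifted <- dplyr::mutate(tibble::as_tibble(init),
                           x = x + 1234, y = y - 987)
  b <- suppressWarnings(refine_level(g, shifted, p, seed = 3))
  # equivariance is exact in exact arithmetic; a short run keeps the
  # inevitable last-bit rounding from being amplified chaotically
  expect_equal(b$x, a$x + 1234, tolerance = 1e-7)
  expect_equal(b$y, a$y - 987, tolerance = 1e-7)
})

test_that("dense matrix path and per-node index queries agree", {
  g <- random_connected_graph(30, 0.15, seed = 31)
  init <- random_layout(g, 100, seed = 4)
  p_dense <- force_params(max_iterations = 3L)
  p_index <- force_params(max_iterations = 3L, dense_threshold = 0L)
  for (backend in c("grid", "mtree", "brute")) {
    p_dense$spatial_index <- backend
    p_index$spatial_index <- backend
    a <- suppressWarnings(refine_level(g, init, p_dense, seed = 6))
    b <- suppressWarnings(refine_level(g, init, p_index, seed = 6))
    expect_equal(b$x, a$x, tolerance = 1e-9)
    expect_equal(b$y, a$y, tolerance = 1e-9)
  }
})

test_that("clustering refinement separates a planted two-module graph", {
  gm <- generate_modular_graph(c(30, 30), p_in = 0.3, p_out = 0.02,
                               seed = 17)
  mod <- setNames(gm$modules$module, gm$modules$node)
  ok <- 0L
  for (seed in 1:20) {
    ly <- multilevel_layout(gm$graph, force_params(), seed = seed)
    pos <- cbind(ly$x, ly$y)
    dmat <- as.matrix(dist(pos))
    same <- outer(mod[ly$node], mod[ly$node], "==")
    ut <- upper.tri(dmat)
    if (mean(dmat[ut & same]) < mean(dmat[ut & !same])) ok <- ok + 1L
  }
  expect_gte(ok, 18)  # >= 90% of runs
})

test_that("force parameter validation rejects nonsense", {
  expect_error(force_params(spring_length = 0))
  expect_error(force_params(cooling_factor = 1))
  expect_error(force_params(tolerance = -1))
})
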