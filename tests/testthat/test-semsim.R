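test_that("ontology construction validates rootedness and acyclicity", {
  onto <- build_ontology(data.frame(term = c("B", "C"), parent = "A"))
  expect_equal(onto$root, "A")
  expect_setequal(onto$ancestors[["B"]], c("B", "A"))

  expect_error(build_ontology(data.frame(term = c("B", "C"),
                                         parent = c("A", "D"))),
               "exactly one root")
  expect_error(build_ontology(data.frame(term = c("A", "B", "A"),
                                         parent = c("B", "A", "R"))),
               "cycle")
})

test_that("information content matches direct annotation counting", {
  onto <- toy_ontology()
  ic <- information_content(onto, toy_annotations())
  icv <- setNames(ic$ic, ic$term)
  expect_equal(icv[["root"]], 0)           # p = 1
  expect_equal(icv[["C"]], -log(1 / 8))    # one of eight genes, no children
  expect_equal(icv[["A"]], -log(4 / 8))    # two leaves of two genes each
  expect_equal(icv[["A1"]], -log(2 / 8))
  # antitone along every is_a edge
  for (t in onto$terms) {
    for (p in onto$parents[[t]]) {
      if (!is.na(icv[[t]])) expect_gte(icv[[t]], icv[[p]])
    }
  }
})

test_that("unannotated terms have undefined IC and are skipped as MICA", {
  onto <- build_ontology(data.frame(term = c("A", "B", "Bx"),
                                    parent = c("root", "root", "B")))
  ann <- tibble::tibble(gene = c("g1", "g2"), term = c("A", "A"))
  ic <- information_content(onto, ann)
  expect_true(is.na(ic$ic[ic$term == "Bx"]))
  expect_equal(ic$ic[ic$term == "root"], 0)
})

test_that("gene similarity: self, root-only overlap, and BMA oracle", {
  onto <- toy_ontology()
  ann <- toy_annotations()
  ic <- information_content(onto, ann)
  # identical single annotations with positive IC
  expect_equal(gene_similarity("y1", "y2", onto, ann, ic), 1)
  # only shared ancestor is the root
  expect_equal(gene_similarity("y1", "y5", onto, ann, ic), 0)

  # hand-enumerated best-match average for multi-term genes:
  # gx = {A1, B1}, gy = {A2, C}; counts unchanged (ic reused)
  icv <- setNames(ic$ic, ic$term)
  lin <- function(t1, t2, mica) 2 * icv[[mica]] / (icv[[t1]] + icv[[t2]])
  ann2 <- tibble::tibble(gene = c(ann$gene, "gx", "gx", "gy", "gy"),
                         term = c(ann$term, "A1", "B1", "A2", "C"))
  s_a1_a2 <- lin("A1", "A2", "A")   # MICA A
  s_a1_c <- 0                       # root only
  s_b1_a2 <- 0
  s_b1_c <- lin("B1", "C", "B")     # MICA B
  best_gx <- c(max(s_a1_a2, s_a1_c), max(s_b1_a2, s_b1_c))
  best_gy <- c(max(s_a1_a2, s_b1_a2), max(s_a1_c, s_b1_c))
  expected <- (mean(best_gx) + mean(best_gy)) / 2
  expect_equal(gene_similarity("gx", "gy", onto, ann2, ic), expected)

  expect_error(gene_similarity("y1", "nope", onto, ann, ic),
               "without annotations")
})

test_that("similarity traces: degenerate, anti-ordered and hand-computed", {
  # all similarities equal -> every trace is that constant, score 0
  tr <- similarity_trace(rep(0.4, 12))
  expect_equal(tr$algorithm, rep(0.4, nrow(tr)))
  expect_equal(tr$optimal, rep(0.4, nrow(tr)))
  expect_equal(tr$random, rep(0.4, nrow(tr)))
  expect_equal(semantic_similarity_score(tr), 0)

  # evaluation order already sorted by descending similarity -> optimal
  s <- seq(1, 0.1, by = -0.1)
  tr <- similarity_trace(s)
  expect_equal(tr$algorithm, tr$optimal)
  expect_equal(semantic_similarity_score(tr), 1)

  # hand-computed cumulative means on a coarse grid
  tr <- similarity_trace(c(0.2, 1.0, 0.5, 0.1), grid_step = 0.25)
  expect_equal(tr$fraction, c(0.25, 0.5, 0.75, 1))
  expect_equal(tr$algorithm, cumsum(c(0.2, 1.0, 0.5, 0.1)) / 1:4)
  expect_equal(tr$optimal, cumsum(c(1.0, 0.5, 0.2, 0.1)) / 1:4)
  expect_equal(tr$random[1], 0.45)
  # traces converge to the random level at 100%
  expect_equal(tr$algorithm[4], tr$random[4])
  expect_equal(tr$optimal[4], tr$random[4])
})

test_that("optimal prefix means dominate every other ordering", {
  set.seed(9)
  s <- runif(30)
  tr_opt <- similarity_trace(sort(s, decreasing = TRUE))
  for (i in 1:10) {
    tr <- similarity_trace(sample(s))
    expect_true(all(tr$optimal - tr$algorithm >= -1e-12))
    expect_lte(semantic_similarity_score(tr),
               semantic_similarity_score(tr_opt) + 1e-12)
  }
})

test_that("random orderings score near zero on average", {
  set.seed(10)
  s <- runif(50)
  scores <- replicate(300, semantic_similarity_score(
    similarity_trace(sample(s))))
  expect_lt(abs(mean(scores)), 0.02)
})

test_that("evaluation_trace ranks edges by layout distance with stable ties", {
  g <- build_graph(data.frame(a = c("y1", "y1", "y3", "y5"),
                              b = c("y2", "y3", "y5", "y7")))
  onto <- toy_ontology()
  ann <- toy_annotations()
  # place nodes so edge distances order as (y1,y2) < (y1,y3) < (y3,y5) < (y5,y7)
  ly <- tibble::tibble(node = c("y1", "y2", "y3", "y5", "y7"),
                       x = c(0, 1, 3, 9, 30), y = 0)
  tr <- evaluation_trace(g, ly, onto, ann, grid_step = 0.25)
  ed <- attr(tr, "edges")
  ord <- order(ed$distance)
  sims <- ed$similarity[ord]
  expect_equal(tr$algorithm, cumsum(sims) / 1:4)
  # score is invariant under rigid motion and uniform scaling
  base <- semantic_similarity_score(tr)
  th <- 0.7
  rot <- tibble::tibble(node = ly$node,
                        x = 3 * (cos(th) * ly$x - sin(th) * ly$y) + 11,
                        y = 3 * (sin(th) * ly$x + cos(th) * ly$y) - 4)
  expect_equal(semantic_similarity_score(
    evaluation_trace(g, rot, onto, ann, grid_step = 0.25)), base)
})

test_that("edges with unannotated endpoints are excluded and counted", {
  g <- build_graph(data.frame(a = c("y1", "y1"), b = c("y2", "zz")))
  onto <- toy_ontology()
  ann <- toy_annotations()
  expect_message(tr <- evaluation_trace(g, tibble::tibble(
    node = c("y1", "y2", "zz"), x = c(0, 1, 2), y = 0), onto, ann),
    "excluded")
  expect_equal(attr(tr, "n_excluded"), 1L)
  expect_equal(attr(tr, "n_edges_evaluated"), 1L)
})

test_that("evaluate_layouts aggregates per-run scores with SEM", {
  small <- generate_modular_graph(c(15, 15), 0.4, 0.05, seed = 3)
  an <- generate_annotations(small$modules, seed = 3)
  lys <- repeat_layout(small$graph, n_runs = 3, base_seed = 1)
  ev <- suppressMessages(
    evaluate_layouts(small$graph, lys, an$ontology, an$annotations))
  expect_equal(ev$n, 3)
  expect_equal(ev$mean, mean(ev$scores$score))
  expect_equal(ev$sem, sd(ev$scores$score) / sqrt(3))

  one <- evaluate_layouts(small$graph, lys[[1]], an$ontology,
                          an$annotations)
  expect_equal(one$sem, 0)
  expect_true(one$single_run)

  same <- evaluate_layouts(small$graph, list(lys[[1]], lys[[1]]),
                           an$ontology, an$annotations)
  expect_equal(same$sem, 0)

  gl <- glance(ev)
  expect_named(gl, c("mean_score", "sem", "n_runs", "single_run"))
  expect_equal(nrow(tidy(ev)), 3)
})

test_that("paired score comparison handles degenerate and regular cases", {
  a <- c(0.5, 0.6, 0.7)
  expect_equal(compare_scores(a, a)$p_value, 1)
  shifted <- compare_scores(a + 1, a)
  expect_equal(shifted$p_value, 1)
  expect_true(shifted$degenerate)

  set.seed(12)
  x <- runif(10)
  y <- runif(10)
  got <- compare_scores(x, y)
  d <- x - y
  t_ref <- mean(d) / (sd(d) / sqrt(10))       # closed-form paired t
  p_ref <- 2 * pt(-abs(t_ref), df = 9)
  expect_equal(got$statistic, t_ref, tolerance = 1e-6)
  expect_equal(got$p_value, p_ref, tolerance = 1e-6)

  expect_error(compare_scores(1:3, 1:4), "equal length")
})
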