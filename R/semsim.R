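#' Build an ontology DAG from is_a edges
#'
#' Represents the term graph of a Gene Ontology namespace (biological
#' process, for layout evaluation). Terms form a rooted DAG over `is_a`
#' relations; ancestor sets (including the term itself) are precomputed so
#' similarity queries are cheap.
#'
#' @param edges A data frame with columns `term`, `parent` (one row per
#'   is_a relation). The root is the unique term never appearing as a
#'   child with a parent.
#' @param namespace Namespace tag carried along (informational).
#' @param name Optional named character vector of term names.
#' @return An object of class `mll_ontology`.
#' @examples
#' onto <- build_ontology(data.frame(term = c("B", "C"), parent = "A"))
#' onto
#' @export
build_ontology <- function(edges, namespace = "biological_process",
                           name = NULL) {
  stopifnot(is.data.frame(edges), all(c("term", "parent") %in% names(edges)))
  edges <- tibble::tibble(term = as.character(edges$term),
                          parent = as.character(edges$parent))
  terms <- sort(unique(c(edges$term, edges$parent)))
  roots <- setdiff(terms, edges$term)
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root, found ",
         length(roots), call. = FALSE)
  }
  ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = data.frame(name = terms))
  if (!igraph::is_dag(ig)) {
    stop("is_a relations contain a cycle", call. = FALSE)
  }
  parents <- lapply(stats::setNames(terms, terms), function(t) {
    edges$parent[edges$term == t]
  })
  # ancestors (self included) in topological order child -> parent
  topo <- igraph::V(ig)$name[as.integer(igraph::topo_sort(ig, mode = "in"))]
  ancestors <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo) {
    ancestors[[t]] <- unique(c(t, unlist(ancestors[parents[[t]]],
                                         use.names = FALSE)))
  }
  structure(
    list(terms = terms, parents = parents, ancestors = ancestors,
         root = roots, namespace = namespace, name = name),
    class = "mll_ontology"
  )
}

#' @export
print.mll_ontology <- function(x, ...) {
  cat(sprintf("<mll_ontology> %d term(s), root %s (%s)\n",
              length(x$terms), x$root, x$namespace))
  invisible(x)
}

# keep only annotation rows whose term exists in the ontology
filter_annotations <- function(ann, onto) {
  stopifnot(is.data.frame(ann), all(c("gene", "term") %in% names(ann)))
  ann <- tibble::tibble(gene = as.character(ann$gene),
                        term = as.character(ann$term))
  bad <- !(ann$term %in% onto$terms)
  if (any(bad)) {
    message(sum(bad), " annotation(s) to unknown terms dropped")
    ann <- ann[!bad, , drop = FALSE]
  }
  dplyr::distinct(ann)
}

#' Information content of ontology terms
#'
#' The annotation probability of a term is the fraction of annotated genes
#' assigned to the term or any of its descendants; its information content
#' is `IC(t) = -ln p(t)`. The root has IC 0 by construction; terms with no
#' annotated gene below them have undefined IC (`NA`) and are excluded
#' from common-ancestor searches.
#'
#' @param onto An `mll_ontology`.
#' @param ann Annotation table with columns `gene`, `term` (direct
#'   annotations).
#' @return A tibble with columns `term`, `n_genes`, `ic` (NA when
#'   unannotated).
#' @export
information_content <- function(onto, ann) {
  ann <- filter_annotations(ann, onto)
  by_gene <- split(ann$term, ann$gene)
  total <- length(by_gene)
  if (total == 0) stop("no usable annotations", call. = FALSE)
  hits <- unlist(lapply(by_gene, function(ts) {
    unique(unlist(onto$ancestors[unique(ts)], use.names = FALSE))
  }), use.names = FALSE)
  counts <- table(factor(hits, levels = onto$terms))
  n <- as.integer(counts)
  ic <- ifelse(n > 0, -log(n / total), NA_real_)
  tibble::tibble(term = onto$terms, n_genes = n, ic = ic)
}

ic_vector <- function(ic) {
  if (is.data.frame(ic)) stats::setNames(ic$ic, ic$term) else ic
}

# Lin (or Resnik) similarity of two terms via the most informative common
# ancestor with defined IC. Identical terms score 1 under Lin even at
# IC 0 (the 0/0 case when every gene carries the same term).
term_similarity <- function(t1, t2, onto, icv,
                            method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (method == "lin" && identical(t1, t2)) return(1)
  common <- intersect(onto$ancestors[[t1]], onto$ancestors[[t2]])
  ics <- icv[common]
  ics <- ics[!is.na(ics)]
  mica <- if (length(ics) > 0) max(ics) else 0
  if (method == "resnik") return(mica)
  denom <- icv[[t1]] + icv[[t2]]
  if (is.na(denom) || denom <= 0) return(0)
  2 * mica / denom
}

#' Semantic similarity between two genes
#'
#' Best-match-average combination of pairwise term similarities between
#' the two genes' direct annotation sets. The default term measure is
#' Lin's, `2 IC(MICA) / (IC(t1) + IC(t2))`, which is bounded in `[0, 1]`
#' (the bound the trace-area normalization relies on); Resnik's `IC(MICA)`
#' is available but unbounded.
#'
#' @param g1,g2 Gene identifiers.
#' @param onto An `mll_ontology`.
#' @param ann Annotation table (`gene`, `term`).
#' @param ic Optional precomputed [information_content()] table (computed
#'   on the fly otherwise).
#' @param method `"lin"` (default) or `"resnik"`.
#' @return Similarity value (in `[0, 1]` for Lin).
#' @export
gene_similarity <- function(g1, g2, onto, ann, ic = NULL,
                            method = c("lin", "resnik")) {
  method <- match.arg(method)
  ann <- filter_annotations(ann, onto)
  if (is.null(ic)) ic <- information_content(onto, ann)
  icv <- ic_vector(ic)
  t1 <- unique(ann$term[ann$gene == g1])
  t2 <- unique(ann$term[ann$gene == g2])
  if (length(t1) == 0 || length(t2) == 0) {
    stop("gene without annotations: ",
         if (length(t1) == 0) g1 else g2, call. = FALSE)
  }
  bma_similarity(t1, t2, onto, icv, method)
}

bma_similarity <- function(t1, t2, onto, icv, method, cache = NULL) {
  sm <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) {
    for (j in seq_along(t2)) {
      sm[i, j] <- cached_term_sim(t1[i], t2[j], onto, icv, method, cache)
    }
  }
  (mean(apply(sm, 1, max)) + mean(apply(sm, 2, max))) / 2
}

cached_term_sim <- function(a, b, onto, icv, method, cache) {
  if (is.null(cache)) return(term_similarity(a, b, onto, icv, method))
  key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- term_similarity(a, b, onto, icv, method)
  cache[[key]] <- val
  val
}

# similarity of every edge whose endpoints are both annotated
edge_similarities <- function(edges, onto, ann, ic, method) {
  icv <- ic_vector(ic)
  terms_of <- split(ann$term, ann$gene)
  ok <- edges$from %in% names(terms_of) & edges$to %in% names(terms_of)
  cache <- new.env(parent = emptyenv())
  sims <- vapply(which(ok), function(i) {
    bma_similarity(unique(terms_of[[edges$from[i]]]),
                   unique(terms_of[[edges$to[i]]]),
                   onto, icv, method, cache)
  }, numeric(1))
  list(evaluable = ok, similarity = sims)
}

#' Cumulative similarity trace from an edge ordering
#'
#' Given edge similarities listed in evaluation order, computes the
#' cumulative mean similarity on a fraction grid, together with the
#' optimal trace (edges re-sorted by descending similarity) and the
#' constant random level (the mean over all edges). All three traces meet
#' at fraction 1.
#'
#' @param similarities Edge similarities in the order the layout ranks
#'   them (ascending distance).
#' @param grid_step Fraction grid resolution, default 0.01.
#' @return An object of class `mll_trace`: a tibble with columns
#'   `fraction`, `algorithm`, `optimal`, `random`, carrying the number of
#'   evaluated edges as attribute `n_edges_evaluated`.
#' @export
similarity_trace <- function(similarities, grid_step = 0.01) {
  m <- length(similarities)
  if (m == 0) stop("no evaluable edges", call. = FALSE)
  stopifnot(grid_step > 0, grid_step <= 1)
  cum_alg <- cumsum(similarities) / seq_len(m)
  opt <- sort(similarities, decreasing = TRUE)
  cum_opt <- cumsum(opt) / seq_len(m)
  fr <- seq(grid_step, 1, by = grid_step)
  if (fr[length(fr)] < 1 - 1e-12) fr <- c(fr, 1)
  idx <- pmin(ceiling(fr * m), m)
  structure(
    tibble::tibble(fraction = fr,
                   algorithm = cum_alg[idx],
                   optimal = cum_opt[idx],
                   random = mean(similarities)),
    n_edges_evaluated = m,
    grid_step = grid_step,
    class = c("mll_trace", class(tibble::tibble()))
  )
}

#' Distance-ranked semantic-similarity trace of a layout
#'
#' The biological evaluation procedure: all evaluable edges (both
#' endpoints annotated) are ranked by the Euclidean distance of their
#' endpoints in the layout, ties broken by edge insertion order, and the
#' cumulative mean semantic similarity of the growing neighbour set is
#' traced against the fraction of edges reviewed. The optimal reference
#' ranks the same edges by descending similarity; the random level is the
#' network-wide mean similarity that every trace converges to at 100%.
#'
#' @param g The `mll_graph` (or edge table) that was laid out.
#' @param layout An `mll_layout` (or data frame `node`, `x`, `y`).
#' @param onto An `mll_ontology`.
#' @param ann Annotation table (`gene`, `term`).
#' @param grid_step Fraction grid resolution.
#' @param ic Optional precomputed [information_content()] table.
#' @param method Term similarity measure, see [gene_similarity()].
#' @return An `mll_trace` (see [similarity_trace()]) with additional
#'   attributes `n_excluded` (edges dropped for unannotated endpoints) and
#'   `edges` (per-edge distance and similarity table).
#' @export
evaluation_trace <- function(g, layout, onto, ann, grid_step = 0.01,
                             ic = NULL, method = c("lin", "resnik")) {
  g <- as_mll_graph(g)
  method <- match.arg(method)
  ann <- filter_annotations(ann, onto)
  if (is.null(ic)) ic <- information_content(onto, ann)
  pos <- layout_matrix(layout, g$nodes)
  es <- edge_similarities(g$edges, onto, ann, ic, method)
  n_excl <- sum(!es$evaluable)
  if (n_excl > 0) {
    message(n_excl, " edge(s) with unannotated endpoint excluded")
  }
  ed <- g$edges[es$evaluable, , drop = FALSE]
  if (nrow(ed) == 0) stop("no evaluable edges", call. = FALSE)
  d <- sqrt((pos[ed$from, 1] - pos[ed$to, 1])^2 +
              (pos[ed$from, 2] - pos[ed$to, 2])^2)
  ord <- order(d)  # stable: ties keep edge insertion order
  tr <- similarity_trace(es$similarity[ord], grid_step)
  attr(tr, "n_excluded") <- n_excl
  attr(tr, "edges") <- tibble::tibble(from = ed$from, to = ed$to,
                                      distance = d,
                                      similarity = es$similarity)
  tr
}

#' Normalized semantic-similarity score of a trace
#'
#' The area between the algorithm's trace and the random level, divided by
#' the area between the optimal trace and the random level (trapezoidal
#' rule on the fraction grid). 1 means the distance ranking reproduces the
#' similarity ranking exactly; values near 0 correspond to a random
#' ordering of the edges. When all similarities are equal the optimal area
#' is 0 and the score is defined as 0.
#'
#' @param trace An `mll_trace`.
#' @return Score (<= 1).
#' @export
semantic_similarity_score <- function(trace) {
  stopifnot(inherits(trace, "mll_trace"))
  f <- trace$fraction
  a_alg <- trapezoid(f, trace$algorithm - trace$random)
  a_opt <- trapezoid(f, trace$optimal - trace$random)
  if (a_opt <= 1e-12) return(0)
  a_alg / a_opt
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Score a set of layouts
#'
#' Computes the semantic-similarity score of each layout of the same graph
#' and summarizes them with mean and standard error of the mean
#' (`sd / sqrt(n)`); with a single layout the SEM is reported as 0 and
#' flagged.
#'
#' @param g Graph, `mll_graph` or edge table.
#' @param layouts A list of layouts (or a single layout).
#' @param onto,ann,grid_step,method See [evaluation_trace()].
#' @return An object of class `mll_eval`; use [generics::tidy()] for the
#'   per-run scores and [generics::glance()] for the summary row.
#' @export
evaluate_layouts <- function(g, layouts, onto, ann, grid_step = 0.01,
                             method = c("lin", "resnik")) {
  method <- match.arg(method)
  if (is.data.frame(layouts)) layouts <- list(layouts)
  stopifnot(length(layouts) >= 1)
  g <- as_mll_graph(g)
  ann <- filter_annotations(ann, onto)
  ic <- information_content(onto, ann)
  scores <- vapply(layouts, function(ly) {
    semantic_similarity_score(
      evaluation_trace(g, ly, onto, ann, grid_step, ic = ic,
                       method = method))
  }, numeric(1))
  n <- length(scores)
  structure(
    list(scores = tibble::tibble(run = seq_len(n), score = scores),
         mean = mean(scores),
         sem = if (n > 1) stats::sd(scores) / sqrt(n) else 0,
         n = n,
         single_run = n == 1),
    class = "mll_eval"
  )
}

#' @export
print.mll_eval <- function(x, ...) {
  cat(sprintf("<mll_eval> %d run(s): mean score %.4f (SEM %.4f)%s\n",
              x$n, x$mean, x$sem,
              if (x$single_run) " [single run, SEM not estimable]" else ""))
  invisible(x)
}

#' Paired comparison of two score lists
#'
#' Two-sided paired t-test on per-run semantic-similarity scores of two
#' layout algorithms evaluated on the same seeds. Zero-variance
#' differences (identical lists, or a constant shift) leave the t
#' statistic undefined; those cases are flagged and reported with p = 1.
#'
#' @param scores_a,scores_b Equal-length numeric vectors (n >= 2).
#' @return A one-row tibble: `mean_diff`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
compare_scores <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score lists must have equal length", call. = FALSE)
  }
  if (length(scores_a) < 2) {
    stop("need at least 2 paired scores", call. = FALSE)
  }
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(mean_diff = mean(d), statistic = NA_real_,
                          df = NA_real_, p_value = 1, degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  tibble::tibble(mean_diff = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 degenerate = FALSE)
}
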