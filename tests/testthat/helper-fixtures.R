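# An 8-node, 10-edge sub-network containing the edges whose contraction is
# traced in the worked coarsening example: pairs (N2,N3), (N4,N8), (N6,N7)
# merge into three metanodes, leaving 5 nodes.
fig1_graph <- function() {
  build_graph(data.frame(
    from = c("N2", "N4", "N6", "N1", "N1", "N5", "N5", "N3", "N7", "N2"),
    to   = c("N3", "N8", "N7", "N2", "N3", "N6", "N7", "N4", "N8", "N6")
  ))
}

fig1_matching <- function(g) {
  structure(
    list(pairs = tibble::tibble(a = c("N2", "N4", "N6"),
                                b = c("N3", "N8", "N7")),
         singletons = c("N1", "N5")),
    class = "mll_matching"
  )
}

# small hand-checkable ontology:
#         root
#        /    \
#       A      B
#      / \    /|\
#     A1 A2 B1 B2 C
toy_ontology <- function() {
  build_ontology(data.frame(
    term = c("A", "B", "A1", "A2", "B1", "B2", "C"),
    parent = c("root", "root", "A", "A", "B", "B", "B")
  ))
}

# genes annotated to single leaves; 8 genes for round IC values
# (A1:2, A2:2, B1:2, B2:1, C:1 -> A:4, B:4, root:8)
toy_annotations <- function() {
  tibble::tibble(
    gene = sprintf("y%d", 1:8),
    term = c("A1", "A1", "A2", "A2", "B1", "B1", "B2", "C")
  )
}

expect_same_graph <- function(a, b) {
  expect_identical(a$nodes, b$nodes)
  expect_identical(as.data.frame(a$edges), as.data.frame(b$edges))
}
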