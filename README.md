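# mllayout

Multilevel force-directed layout and biological evaluation of interaction
networks, in R.

Large physical (protein–protein, co-complex) and genetic (E-MAP, SGA)
interaction networks are hard to draw: a plain spring embedder applied to a
few thousand densely connected nodes tends to collapse into an uninformative
"hairball" that hides the hierarchical, modular organisation these networks
are known to have. `mllayout` implements two things for such networks:

1. **A multilevel layout algorithm (MLL / MLL-C).** The graph G₀ is
   recursively coarsened into G₀, G₁, …, G_L by randomized weighted edge
   matching: a random node is matched with the unmatched neighbour of
   smallest weight (optionally weight × (1 + degree), which protects hubs in
   star-like networks), matched pairs contract into metanodes whose weight
   w counts the original nodes they contain, and for a connected input the
   coarsest graph G_L is two nodes joined by one edge. Uncoarsening then
   walks back down: metanode members start at their metanode's position and
   each level is relaxed with a node-weighted Fruchterman–Reingold scheme —
   repulsion C·w·k²/d, attraction d²/k, displacement capped by a
   geometrically cooled temperature, with k the natural spring length and C
   the repulsion multiplier. With the clustering option on (MLL-C, the
   default), forces are modulated by local clustering coefficients
   (attraction ×(1 + α·mean CC) between neighbours, repulsion
   ×(1 + β·max CC) between non-neighbours) to pull dense modules together
   and push distinct modules apart. Neighbour fetching during force
   calculation goes through an exact metric spatial index (M-tree-style
   ball tree, uniform grid, or brute-force scan).

2. **A biological evaluation of layout quality.** Given a Gene Ontology
   (OBO) and annotations (GAF, biological-process aspect), the edges of a
   layout are ranked by the Euclidean distance of their endpoints and the
   cumulative mean Lin/best-match-average semantic similarity of the growing
   neighbour set is traced against the fraction of edges reviewed. The
   trace is compared with the theoretical optimum (edges ranked by
   similarity itself) and the random level (the network-wide mean, which
   every trace reaches at 100%). The **semantic similarity score** is the
   area between the algorithm's trace and the random level divided by the
   area between the optimal trace and the random level: 1 means the layout
   distance ranking reproduces the similarity ranking, ≈0 means it is no
   better than random. Scores from repeated seeded runs are averaged with
   SEM, and algorithms are compared with a two-sided paired t-test.

A synthetic-data module generates planted-partition modular graphs and
module-correlated toy ontologies/annotations, so the whole pipeline is
testable offline.

## Worked example

```r
library(mllayout)

# a 4-module benchmark network with module-correlated annotations
b <- synthetic_benchmark(seed = 1)
summarize_network(b$graph)
#> # A tibble: 1 × 6
#>   n_nodes n_edges density mean_degree sd_degree mean_cc
#>     <int>   <int>   <dbl>       <dbl>     <dbl>   <dbl>
#> 1     400    5236  0.0656        26.2      4.54   0.132

# multilevel layout with clustering option (MLL-C), fixed seed
ly <- multilevel_layout(b$graph, force_params(), seed = 1)
attr(ly, "hierarchy_depth")
#> [1] 8

# biological evaluation against the bundled ontology/annotations
tr <- evaluation_trace(b$graph, ly, b$ontology, b$annotations)
semantic_similarity_score(tr)
#> [1] 0.3403421
tr$random[1]            # network-wide mean similarity (random level)
#> [1] 0.4573299

# a uniformly random layout of the same graph scores near zero
rl <- random_layout(b$graph, 100, seed = 2)
semantic_similarity_score(evaluation_trace(b$graph, rl, b$ontology,
                                           b$annotations))
#> [1] -0.01222909

autoplot(tr)                      # evaluation chart
autoplot(ly, graph = b$graph,     # drawn layout, coloured by module
         node_colour = b$modules)
```

The MLL-C score of 0.34 says the layout's distance ranking recovers about a
third of the semantic ordering achievable by a perfect ranking, while the
random layout sits at ≈0 — the layout is carrying real biological signal,
not just aesthetics.

### Command line

```sh
mllayout simulate --modules 4 --size 100 --seed 1 --out net.sif,go.obo,ann.gaf
mllayout layout net.sif --out coords.tsv --seed 1 --runs 10
mllayout stats net.sif
mllayout evaluate net.sif coords_run1.tsv --obo go.obo --gaf ann.gaf \
         --out chart.png,scores.tsv
```

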