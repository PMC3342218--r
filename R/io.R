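#' Read an interaction network file
#'
#' Supports the Cytoscape SIF format (`source interaction target
#' [target ...]` rows, one edge per listed target; the interaction type is
#' parsed but discarded — layout is type-blind) and plain two-column edge
#' lists (extra columns ignored, `#` comment and blank lines skipped).
#' The result passes through [build_graph()] normalisation, so duplicate
#' edges and self-loops are dropped.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.sif` is SIF, anything else an
#'   edge list), `"sif"` or `"edgelist"`.
#' @return An `mll_graph`.
#' @export
read_network <- function(path, format = c("auto", "sif", "edgelist")) {
  format <- match.arg(format)
  check_readable(path)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) {
      "sif"
    } else {
      "edgelist"
    }
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  from <- character(0)
  to <- character(0)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (format == "sif") {
      if (length(tok) == 1L) {
        warning("line ", i, ": isolated node '", tok, "' skipped",
                call. = FALSE)
        next
      }
      if (length(tok) == 2L) {
        stop("line ", i, ": malformed SIF row (source interaction target)",
             call. = FALSE)
      }
      from <- c(from, rep(tok[1], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    } else {
      if (length(tok) < 2L) {
        stop("line ", i, ": malformed edge-list row", call. = FALSE)
      }
      from <- c(from, tok[1])
      to <- c(to, tok[2])
    }
  }
  if (length(from) == 0L) {
    stop("no edges found in ", path, call. = FALSE)
  }
  build_graph(data.frame(from = from, to = to))
}

#' Write a network file
#'
#' @param g An `mll_graph` or edge table.
#' @param path Output path.
#' @param format `"sif"` (rows `from pp to`) or `"edgelist"`
#'   (tab-separated pairs).
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("sif", "edgelist")) {
  g <- as_mll_graph(g)
  format <- match.arg(format)
  lines <- if (format == "sif") {
    paste(g$edges$from, "pp", g$edges$to, sep = "\t")
  } else {
    paste(g$edges$from, g$edges$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write layout coordinate tables
#'
#' Tab-separated `node_id`, `x`, `y` with a header line. Coordinates are
#' serialised with 6 significant digits in C-locale decimal notation, so
#' files are bit-comparable across platforms and round trips preserve
#' coordinates to ~1e-5 relative error.
#'
#' @param layout An `mll_layout` or data frame `node`, `x`, `y`.
#' @param path File path.
#' @param graph Optional `mll_graph`; on read, a node-set mismatch between
#'   file and graph raises a warning.
#' @return `write_layout()`: `path`, invisibly. `read_layout()`: an
#'   `mll_layout`.
#' @export
write_layout <- function(layout, path) {
  lines <- c("node_id\tx\ty",
             sprintf("%s\t%.6g\t%.6g", layout$node, layout$x, layout$y))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path, graph = NULL) {
  check_readable(path)
  tb <- utils::read.delim(path, header = TRUE, colClasses =
                            c("character", "numeric", "numeric"))
  names(tb) <- c("node", "x", "y")
  if (!is.null(graph)) {
    graph <- as_mll_graph(graph)
    if (!setequal(tb$node, graph$nodes)) {
      warning("layout file nodes do not match the graph", call. = FALSE)
    }
  }
  new_mll_layout(tibble::as_tibble(tb), spring_length = NA_real_)
}

#' Read an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas (id, name, namespace, `is_a`; trailing `!`
#' comments stripped), skips obsolete terms, optionally filters to one
#' namespace, and validates the result as a single-rooted DAG.
#'
#' @param path OBO file path.
#' @param namespace Optional namespace filter (e.g.
#'   `"biological_process"`); `NULL` keeps all terms.
#' @return An `mll_ontology`.
#' @export
read_obo <- function(path, namespace = NULL) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id) && !isTRUE(cur$obsolete)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(is_a = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || ln == "") next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) < 3) next
    val <- sub("\\s*!.*$", "", kv[3])
    switch(kv[2],
      id = cur$id <- val,
      name = cur$name <- val,
      namespace = cur$namespace <- val,
      is_a = cur$is_a <- c(cur$is_a, val),
      is_obsolete = cur$obsolete <- identical(val, "true")
    )
  }
  terms <- flush(cur, terms)
  if (!is.null(namespace)) {
    terms <- Filter(function(t) identical(t$namespace, namespace), terms)
  }
  ids <- names(terms)
  edges <- dplyr::bind_rows(lapply(terms, function(t) {
    isa <- intersect(t$is_a, ids)
    if (length(isa) == 0) return(NULL)
    tibble::tibble(term = t$id, parent = isa)
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    stop("no is_a relations found in ", path, call. = FALSE)
  }
  nm <- vapply(terms, function(t) t$name %||% t$id, character(1))
  ns <- vapply(terms, function(t) t$namespace %||% "", character(1))
  build_ontology(edges,
                 namespace = namespace %||% names(sort(table(ns),
                                                       decreasing = TRUE))[1],
                 name = nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_readable <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write an ontology as OBO 1.2
#'
#' @param onto An `mll_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in onto$terms) {
    writeLines(c(
      "[Term]",
      paste0("id: ", t),
      paste0("name: ", if (!is.null(onto$name)) onto$name[[t]] else t),
      paste0("namespace: ", onto$namespace),
      if (length(onto$parents[[t]]) > 0) {
        paste0("is_a: ", onto$parents[[t]])
      },
      ""
    ), con)
  }
  invisible(path)
}

#' Read gene annotations from a GAF 2.x file
#'
#' Keeps columns 2 (gene id) and 5 (term id) of rows whose aspect (column
#' 9) matches; `!` comment lines are skipped. With an ontology supplied,
#' annotations to unknown terms are dropped with a message.
#'
#' @param path GAF file path.
#' @param aspect Aspect filter, default `"P"` (biological process).
#' @param onto Optional `mll_ontology` to validate terms against.
#' @return A tibble with columns `gene`, `term`.
#' @export
read_gaf <- function(path, aspect = "P", onto = NULL) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  if (length(lines) == 0) stop("no annotation rows in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 9
  if (any(short)) {
    stop("malformed GAF row (fewer than 9 columns) at data line ",
         which(short)[1], call. = FALSE)
  }
  gene <- vapply(parts, `[[`, character(1), 2)
  term <- vapply(parts, `[[`, character(1), 5)
  asp <- vapply(parts, `[[`, character(1), 9)
  ann <- dplyr::distinct(
    tibble::tibble(gene = gene, term = term)[asp == aspect, ])
  if (!is.null(onto)) ann <- filter_annotations(ann, onto)
  ann
}

#' Write annotations as GAF 2.1
#'
#' @param ann Annotation tibble (`gene`, `term`).
#' @param path Output path.
#' @param aspect Aspect code written in column 9.
#' @param taxon Taxon tag for column 13.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, path, aspect = "P", taxon = "taxon:4932") {
  rows <- sprintf(
    "MLL\t%s\t%s\t\t%s\tMLL:0000001\tIEA\t\t%s\t\t\tgene_product\t%s\t20120326\tMLL\t\t",
    ann$gene, ann$gene, ann$term, aspect, taxon
  )
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}
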