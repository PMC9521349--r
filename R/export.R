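#' Export a learned network
#'
#' Writes the DAG as Graphviz DOT and/or GraphML with per-node attributes
#' (gene symbol and, when supplied, marginal alteration frequency).
#' GraphML goes through igraph; the DOT file is written by a small
#' formatter so node attributes are carried.
#'
#' @param dag A [GeneDag-class].
#' @param dotPath,graphmlPath output paths; `NULL` skips a format.
#' @param frequencies optional named numeric of per-gene marginal
#'   frequencies attached as node attributes.
#' @return invisibly, a character vector of the files written.
#' @export
exportNetwork <- function(dag, dotPath = NULL, graphmlPath = NULL,
                          frequencies = NULL) {
  written <- character(0)
  edges <- dagEdges(dag)
  if (!is.null(dotPath)) {
    lines <- c("digraph comutation_network {", "  node [shape=ellipse];")
    for (v in dag@nodes) {
      fr <- if (!is.null(frequencies) && v %in% names(frequencies))
        sprintf(", frequency=\"%.4f\"", frequencies[[v]]) else ""
      lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"%s];", v, v, fr))
    }
    if (nrow(edges))
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                                edges[, "from"], edges[, "to"]))
    lines <- c(lines, "}")
    writeLines(lines, dotPath)
    written <- c(written, dotPath)
  }
  if (!is.null(graphmlPath)) {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(dag@nodes)
    if (nrow(edges))
      g <- igraph::add_edges(g, as.vector(t(edges)))
    igraph::V(g)$gene <- dag@nodes
    if (!is.null(frequencies))
      igraph::V(g)$frequency <-
        as.numeric(frequencies[dag@nodes])
    igraph::write_graph(g, graphmlPath, format = "graphml")
    written <- c(written, graphmlPath)
  }
  invisible(written)
}

#' Dump fitted conditional probability tables as TSV
#'
#' One row per (node, parent configuration): parents are semicolon-joined
#' in CPT bit order and the configuration column gives the parent states
#' as a bit string (first parent = least-significant bit).
#'
#' @param cpts A [CptSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCpts <- function(cpts, path) {
  rows <- list()
  for (v in names(cpts@cpts)) {
    e <- cpts@cpts[[v]]
    k <- length(e$parents)
    for (cfg in 0:(2^k - 1)) {
      bits <- if (k) paste(rev(as.integer(intToBits(cfg))[seq_len(k)]),
                           collapse = "") else ""
      rows[[length(rows) + 1L]] <- data.frame(
        node = v, parents = paste(e$parents, collapse = ";"),
        config = bits, p1 = e$p1[cfg + 1], stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Moralized skeleton adjacency of a DAG
#'
#' Undirected adjacency after moralization (marry co-parents, drop
#' directions); used to ask whether two genes are connected in the
#' learned structure irrespective of edge orientation.
#'
#' @param dag A [GeneDag-class].
#' @return logical adjacency matrix.
#' @export
moralizedSkeleton <- function(dag) {
  n <- length(dag@nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(dag@nodes, dag@nodes))
  for (v in dag@nodes) {
    pa <- dag@parents[[v]]
    for (p in pa) { adj[p, v] <- TRUE; adj[v, p] <- TRUE }
    if (length(pa) > 1)
      for (i in seq_along(pa)) for (j in seq_along(pa))
        if (i != j) adj[pa[i], pa[j]] <- TRUE
  }
  adj
}
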