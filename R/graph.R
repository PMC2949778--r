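#' Export a connectivity graph
#'
#' Supported formats: `"json"` (full edge list with `source`, `target`,
#' `strength`, `in_mst`, plus nodes and hubs; round-trips through
#' [import_graph()]), `"dot"` (Graphviz source showing the spanning tree
#' only, edge labels printed with 2 decimals) and `"graphml"` (all edges
#' with `strength`/`in_mst` attributes, via igraph).
#'
#' @param g A `connectivity_graph`.
#' @param path Output file path.
#' @param format One of `"json"`, `"dot"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("json", "dot", "graphml")) {
  format <- match.arg(format)
  switch(format,
    json = {
      jsonlite::write_json(
        list(nodes = g$nodes, hubs = g$hubs,
             edges = data.frame(source = g$edges$from, target = g$edges$to,
                                strength = g$edges$strength,
                                in_mst = g$edges$in_mst,
                                stringsAsFactors = FALSE)),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    dot = {
      lines <- c("graph connectivity {",
                 "  node [shape=ellipse];",
                 sprintf("  \"%s\";", g$nodes),
                 sprintf("  \"%s\" -- \"%s\" [label=\"%.2f\"];",
                         g$mst_edges$from, g$mst_edges$to,
                         g$mst_edges$strength),
                 "}")
      writeLines(lines, path)
    },
    graphml = {
      ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                          vertices = g$nodes)
      igraph::write_graph(ig, path, format = "graphml")
    })
  invisible(path)
}

#' Re-import a JSON-exported connectivity graph
#'
#' @param path A JSON file written by [export_graph()].
#' @return A `connectivity_graph`.
#' @export
import_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- data.frame(from = obj$edges$source, to = obj$edges$target,
                      strength = obj$edges$strength,
                      in_mst = obj$edges$in_mst, stringsAsFactors = FALSE)
  mst <- edges[edges$in_mst, c("from", "to", "strength")]
  rownames(mst) <- NULL
  structure(list(nodes = obj$nodes, edges = edges, mst_edges = mst,
                 hubs = obj$hubs),
            class = "connectivity_graph")
}
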