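# GraphML export for typed biological networks, delegated to igraph.

#' Write a typed node/edge list as GraphML
#'
#' Nodes carry `label` and `biopax_class` attributes; edges carry an
#' `edge_type` attribute. Both survive a round-trip through
#' [read_graphml()].
#'
#' @param nodes Tibble with columns `id` and optionally `label`,
#'   `biopax_class`.
#' @param edges Tibble with columns `from`, `to` and optionally `edge_type`.
#'   Endpoints must appear in `nodes$id`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(nodes, edges, path) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (nrow(nodes) > 0 && !"label" %in% names(nodes)) nodes$label <- nodes$id
  if (nrow(nodes) > 0 && !"biopax_class" %in% names(nodes)) {
    nodes$biopax_class <- NA_character_
  }
  if (nrow(edges) > 0 && !"edge_type" %in% names(edges)) {
    edges$edge_type <- NA_character_
  }
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(dangling) > 0) {
    abort(paste0("Edge endpoint not in node set: ", dangling[1]))
  }
  g <- if (nrow(nodes) == 0) {
    igraph::make_empty_graph(directed = TRUE)
  } else {
    igraph::graph_from_data_frame(
      d = edges[, intersect(c("from", "to", "edge_type"), names(edges))],
      directed = TRUE,
      vertices = nodes[, intersect(c("id", "label", "biopax_class"),
                                   names(nodes))]
    )
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file back into node and edge tibbles
#'
#' @param path Path to a GraphML file.
#' @return A list with tibbles `nodes` (`id`, `label`, `biopax_class`) and
#'   `edges` (`from`, `to`, `edge_type`).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  ids <- va$name %||% va$id %||% character()
  nodes <- tibble::tibble(
    id = as.character(ids),
    label = as.character(va$label %||% rep(NA_character_, length(ids))),
    biopax_class = as.character(va$biopax_class %||%
                                  rep(NA_character_, length(ids)))
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- tibble::tibble(
    from = as.character(el[, 1]),
    to = as.character(el[, 2]),
    edge_type = as.character(igraph::edge_attr(g, "edge_type") %||%
                               rep(NA_character_, nrow(el)))
  )
  list(nodes = nodes, edges = edges)
}
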