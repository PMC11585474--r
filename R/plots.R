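# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_segment geom_point
#'   geom_label labs theme_minimal facet_wrap arrow unit position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a (normalized) class census
#'
#' Grouped bars of the per-class instance counts, or of the
#' percentage-of-maximum values when the census has been normalized with
#' [normalize_census()] (the tabular equivalent of the radar comparison of
#' database exports).
#'
#' @param object A `biopax_census` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biopax_census <- function(object, ...) {
  df <- tibble::as_tibble(object)
  value <- if ("pct" %in% names(df)) "pct" else "n"
  df$class <- factor(df$class, levels = CENSUS_CLASSES)
  ggplot(df, aes(x = .data$class, y = .data[[value]], fill = .data$source)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL,
         y = if (value == "pct") "% of per-class maximum" else "instances",
         fill = "export") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a mapping-audit partition
#'
#' One stacked bar splitting the entity set into mapped / no-reference /
#' reference-without-target.
#'
#' @param object A `mapping_audit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapping_audit <- function(object, ...) {
  df <- tibble::tibble(
    outcome = factor(c("mapped", "no reference", "reference, no target"),
                     levels = c("reference, no target", "no reference",
                                "mapped")),
    n = c(object$n_mapped, object$n_no_reference,
          object$n_reference_no_target)
  )
  ggplot(df, aes(x = paste(object$entity_class, "→", object$target_db),
                 y = .data$n, fill = .data$outcome)) +
    geom_col() +
    labs(x = NULL, y = "entities", fill = NULL) +
    theme_minimal()
}

#' Plot an abstract step-sequence graph
#'
#' Nodes are the root's direct reactions and sub-pathways; edges are the
#' three derived kinds. Laid out with igraph's Fruchterman-Reingold
#' algorithm (seeded, so a given graph always draws the same way).
#'
#' @param object An `abstract_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abstract_graph <- function(object, ...) {
  nodes <- abstract_nodes(object)
  if (nrow(nodes) == 0) {
    return(ggplot() + theme_minimal() + labs(title = "empty abstract graph"))
  }
  g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                     directed = TRUE, vertices = nodes["id"])
  lay <- withr::with_seed(1L, igraph::layout_with_fr(g))
  pos <- tibble::tibble(id = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  nodes <- dplyr::left_join(nodes, pos, by = "id")
  edges <- object$edges |>
    dplyr::left_join(pos, by = c(from = "id")) |>
    dplyr::left_join(pos, by = c(to = "id"), suffix = c("", "end"))
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linetype = .data$kind,
                     colour = .data$kind),
                 arrow = arrow(length = unit(2, "mm"))) +
    geom_label(data = nodes,
               aes(x = .data$x, y = .data$y, label = .data$label,
                   fill = .data$biopax_class), size = 2.6) +
    theme_minimal() +
    labs(x = NULL, y = NULL, fill = "node", colour = "edge",
         linetype = "edge")
}
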