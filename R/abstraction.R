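# Step-sequence abstraction: collapse PathwayStep scaffolding into a
# high-level graph over a root pathway's direct biochemical reactions and
# sub-pathways, with three typed derived edge kinds minted under the
# http://abstraction/ namespace.

ABSTRACT_EDGE_KINDS <- c("NextStepBiochemicalReaction",
                         "NextStepPathwayFromReaction",
                         "NextStepPathwayBetweenPathways")

#' Direct reaction and sub-pathway components of a pathway
#'
#' Partitions the objects of the pathway's `bp3:pathwayComponent` triples by
#' type: conversions (BiochemicalReaction and other Conversion descendants)
#' versus sub-pathways.
#'
#' @param graph A [biopax_graph()].
#' @param pathway IRI of a Pathway instance.
#' @return A list with character vectors `reactions` and `pathways`.
#' @export
direct_components <- function(graph, pathway) {
  .assert_pathway(graph, pathway)
  comps <- .objects_of(graph$triples, pathway, bp3("pathwayComponent"))
  conversions <- instances_of(graph, "Conversion", include_subclasses = TRUE)
  pathways <- instances_of(graph, "Pathway")
  list(
    reactions = sort(intersect(comps, conversions)),
    pathways = sort(intersect(comps, pathways))
  )
}

#' Biochemical reactions attached to a pathway step
#'
#' Returns the `bp3:stepProcess` objects of the step that are Conversion
#' descendants. Control processes (Catalysis, Control) grouped into the same
#' step are excluded: they regulate the reaction, they are not part of the
#' reaction sequence itself.
#'
#' @param graph A [biopax_graph()].
#' @param step IRI of a PathwayStep instance.
#' @return Character vector of reaction IRIs.
#' @export
reactions_of_step <- function(graph, step) {
  if (!step %in% instances_of(graph, "PathwayStep")) {
    abort(paste0("Not a PathwayStep instance in this graph: ", step))
  }
  procs <- .objects_of(graph$triples, step, bp3("stepProcess"))
  conversions <- instances_of(graph, "Conversion", include_subclasses = TRUE)
  sort(intersect(procs, conversions))
}

#' Is a reaction part of a pathway's membership closure?
#'
#' A reaction belongs to a pathway when it is reachable through
#' `bp3:pathwayComponent` (transitively across nested sub-pathways) or via
#' `bp3:pathwayOrder` followed by `bp3:stepProcess`.
#'
#' @param graph A [biopax_graph()].
#' @param reaction,pathway IRIs.
#' @return `TRUE` or `FALSE`.
#' @export
reaction_in_pathway <- function(graph, reaction, pathway) {
  reaction %in% .pathway_reaction_closure(graph, pathway)
}

.pathway_reaction_closure <- function(graph, pathway) {
  tr <- graph$triples
  pc <- bp3("pathwayComponent")
  po <- bp3("pathwayOrder")
  sp <- bp3("stepProcess")
  pathways <- instances_of(graph, "Pathway")

  seen_pw <- pathway
  frontier <- pathway
  members <- character()
  while (length(frontier) > 0) {
    comps <- .objects_of(tr, frontier, pc)
    steps <- .objects_of(tr, frontier, po)
    members <- union(members, union(comps, .objects_of(tr, steps, sp)))
    frontier <- setdiff(intersect(comps, pathways), seen_pw)
    seen_pw <- c(seen_pw, frontier)
  }
  members
}

# Reaction-bearing successor steps of s, treating control-only steps
# (reactions_of_step == empty) as transparent links in the chain.
.effective_successors <- function(step, next_of, step_reactions,
                                  chain_through) {
  out <- character()
  seen <- character()
  frontier <- next_of[[step]] %||% character()
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    has_rxn <- vapply(frontier, function(s)
      length(step_reactions[[s]] %||% character()) > 0, TRUE)
    out <- c(out, frontier[has_rxn])
    frontier <- if (chain_through) {
      unique(unlist(lapply(frontier[!has_rxn], function(s)
        next_of[[s]] %||% character())))
    } else {
      character()
    }
  }
  unique(out)
}

#' Abstract a pathway's step scaffolding into a reaction/pathway sequence
#'
#' Builds the high-level view of a root pathway: nodes are the root's
#' direct biochemical reactions and direct sub-pathways, and every
#' `bp3:nextStep` pair of steps inside the root's closure induces derived
#' edges between the reactions the steps carry. For a step pair with
#' reactions r1 and r2: if both are direct reactions of the root they are
#' joined by a `NextStepBiochemicalReaction` edge; if r1 is direct and r2
#' belongs to a direct sub-pathway, r1 is joined to that sub-pathway
#' (`NextStepPathwayFromReaction`); if r1 and r2 belong to two different
#' direct sub-pathways, the sub-pathways are joined
#' (`NextStepPathwayBetweenPathways`). PathwaySteps never survive into the
#' result, self-loops are suppressed, and duplicate derived edges collapse.
#'
#' @param graph A [biopax_graph()].
#' @param root IRI of a Pathway instance.
#' @param chain_through_controls Treat steps that carry only control
#'   processes as transparent, linking their predecessors' reactions to
#'   their successors' reactions? Default `TRUE`.
#' @return An object of class `abstract_graph`: `root`, `reaction_nodes`,
#'   `pathway_nodes`, an `edges` tibble (`from`, `to`, `kind`), the
#'   abstraction namespace, and `n_reverse_skipped` (count of step pairs
#'   running from a sub-pathway reaction back to a direct reaction, which
#'   the abstraction deliberately does not encode).
#' @examples
#' abstract_step_sequence(rna_pol2_fixture(), rna_pol2_root())
#' @export
abstract_step_sequence <- function(graph, root, chain_through_controls = TRUE) {
  .assert_pathway(graph, root)
  comps <- direct_components(graph, root)
  closure <- extract_pathway_closure(graph, root)
  tr <- graph$triples
  steps <- intersect(closure$member_nodes, instances_of(graph, "PathwayStep"))

  step_reactions <- stats::setNames(
    lapply(steps, function(s) reactions_of_step(graph, s)), steps)
  ns_edges <- tr[tr$predicate == bp3("nextStep") & !tr$object_is_literal &
                   tr$subject %in% steps & tr$object %in% steps, ,
                 drop = FALSE]
  next_of <- split(ns_edges$object, ns_edges$subject)

  # classify a reaction: direct reaction of root wins over sub-pathway
  # membership; otherwise list the direct sub-pathways that contain it
  sub_members <- stats::setNames(
    lapply(comps$pathways, function(p) .pathway_reaction_closure(graph, p)),
    comps$pathways)
  subs_of <- function(r) {
    comps$pathways[vapply(comps$pathways,
                          function(p) r %in% sub_members[[p]], TRUE)]
  }

  from <- character(); to <- character(); kind <- character()
  n_reverse <- 0L
  for (s1 in steps) {
    r1s <- step_reactions[[s1]]
    if (length(r1s) == 0) next
    succ <- .effective_successors(s1, next_of, step_reactions,
                                  chain_through_controls)
    for (s2 in succ) {
      for (r1 in r1s) {
        for (r2 in step_reactions[[s2]]) {
          r1_direct <- r1 %in% comps$reactions
          r2_direct <- r2 %in% comps$reactions
          if (r1_direct && r2_direct) {
            if (r1 != r2) {
              from <- c(from, r1); to <- c(to, r2)
              kind <- c(kind, "NextStepBiochemicalReaction")
            }
          } else if (r1_direct) {
            for (sp in subs_of(r2)) {
              from <- c(from, r1); to <- c(to, sp)
              kind <- c(kind, "NextStepPathwayFromReaction")
            }
          } else {
            sp1s <- subs_of(r1)
            if (r2_direct) {
              if (length(sp1s) > 0) n_reverse <- n_reverse + 1L
              next
            }
            for (sp1 in sp1s) {
              for (sp2 in setdiff(subs_of(r2), sp1)) {
                from <- c(from, sp1); to <- c(to, sp2)
                kind <- c(kind, "NextStepPathwayBetweenPathways")
              }
            }
          }
        }
      }
    }
  }

  edges <- dplyr::distinct(tibble::tibble(from = from, to = to, kind = kind))
  edges <- dplyr::arrange(edges, .data$from, .data$to, .data$kind)
  structure(
    list(
      root = root,
      reaction_nodes = comps$reactions,
      pathway_nodes = comps$pathways,
      edges = edges,
      abs_namespace = ABS_NS,
      n_reverse_skipped = n_reverse
    ),
    class = "abstract_graph"
  )
}

#' @export
print.abstract_graph <- function(x, ...) {
  cat("<abstract_graph> root: ", x$root, "\n", sep = "")
  cat("  ", length(x$reaction_nodes), " reaction nodes, ",
      length(x$pathway_nodes), " sub-pathway nodes, ",
      nrow(x$edges), " derived edges\n", sep = "")
  if (x$n_reverse_skipped > 0) {
    cat("  (", x$n_reverse_skipped,
        " sub-pathway-to-direct-reaction step pairs not encoded)\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.abstract_graph <- function(x, ...) x$edges

#' @export
glance.abstract_graph <- function(x, ...) {
  tibble::tibble(
    root = x$root,
    n_reaction_nodes = length(x$reaction_nodes),
    n_pathway_nodes = length(x$pathway_nodes),
    n_edges = nrow(x$edges),
    n_reverse_skipped = x$n_reverse_skipped
  )
}

#' Node table of an abstract graph
#' @param x An `abstract_graph`.
#' @return Tibble with `id`, `label`, `biopax_class`.
#' @export
abstract_nodes <- function(x) {
  tibble::tibble(
    id = c(x$reaction_nodes, x$pathway_nodes),
    label = basename(c(x$reaction_nodes, x$pathway_nodes)),
    biopax_class = c(rep("BiochemicalReaction", length(x$reaction_nodes)),
                     rep("Pathway", length(x$pathway_nodes)))
  )
}

#' Serialize an abstract graph as RDF triples
#'
#' The abstraction stays a Semantic-Web object: reaction-to-reaction edges
#' become `abs:NextStepBiochemicalReaction` statements and both
#' pathway-linking edge kinds become `abs:NextStepPathway` statements, with
#' `abs:` = `http://abstraction/`.
#'
#' @param x An `abstract_graph`.
#' @return A [biopax_graph()] carrying the derived statements plus
#'   `rdf:type` statements for the nodes.
#' @export
abstract_to_triples <- function(x) {
  nodes <- abstract_nodes(x)
  pred <- ifelse(x$edges$kind == "NextStepBiochemicalReaction",
                 paste0(ABS_NS, "NextStepBiochemicalReaction"),
                 paste0(ABS_NS, "NextStepPathway"))
  tr <- dplyr::bind_rows(
    rdf_triples(nodes$id, RDF_TYPE, bp3(nodes$biopax_class)),
    rdf_triples(x$edges$from, pred, x$edges$to)
  )
  biopax_graph(tr, namespaces = c(abs = ABS_NS), check_vocabulary = FALSE)
}

#' Write an abstract graph as GraphML
#'
#' @param x An `abstract_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstract_graphml <- function(x, path) {
  write_graphml(abstract_nodes(x), x$edges |>
                  dplyr::rename(edge_type = "kind"), path)
}
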