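# Pathway subgraph extraction by property closure, and filtered low-level
# views (class whitelist + property blacklist).

DEFAULT_FOLLOW_PROPERTIES <- c(
  "pathwayComponent", "pathwayOrder", "nextStep", "stepProcess",
  "left", "right", "controller", "controlled", "component",
  "entityReference", "xref"
)

#' Traversal policy for pathway extraction
#'
#' @param follow_properties BioPAX properties (local names or IRIs) whose
#'   outgoing edges the closure follows. The default covers the properties
#'   that connect a pathway to its steps, reactions, controls, participants
#'   and references.
#' @param max_depth Maximum traversal depth from the root (`Inf` for the
#'   full closure; `0` keeps the root alone).
#' @return An object of class `traversal_policy`.
#' @export
traversal_policy <- function(follow_properties = DEFAULT_FOLLOW_PROPERTIES,
                             max_depth = Inf) {
  props <- bp3_local(follow_properties)
  unknown <- setdiff(props, .biopax_property_names)
  if (length(unknown) > 0) {
    abort(paste0("Not a BioPAX property: ", paste(unknown, collapse = ", ")))
  }
  stopifnot(length(max_depth) == 1, max_depth >= 0)
  structure(list(follow_properties = props, max_depth = max_depth),
            class = "traversal_policy")
}

.assert_pathway <- function(graph, root) {
  if (!root %in% instances_of(graph, "Pathway")) {
    abort(paste0("Not a Pathway instance in this graph: ", root))
  }
}

#' Extract the subgraph of a pathway by breadth-first closure
#'
#' Starting from a pathway root, follows the policy's properties outward
#' (subject to object) and collects the visited nodes. The returned
#' subgraph keeps the triples whose subject is a member and whose predicate
#' is a followed property with a member object; `rdf:type` and
#' `bp3:displayName` triples of members are always retained so downstream
#' census and abstraction keep working.
#'
#' @param graph A [biopax_graph()].
#' @param root IRI of a Pathway instance in `graph`.
#' @param policy A [traversal_policy()].
#' @return A `biopax_subgraph`: a [biopax_graph()] with extra fields `root`
#'   and `member_nodes`.
#' @examples
#' g <- rna_pol2_fixture()
#' sub <- extract_pathway_closure(g, rna_pol2_root())
#' length(sub$member_nodes)
#' @export
extract_pathway_closure <- function(graph, root,
                                    policy = traversal_policy()) {
  .assert_pathway(graph, root)
  tr <- graph$triples
  follow <- bp3(policy$follow_properties)
  edges <- tr[tr$predicate %in% follow & !tr$object_is_literal, ,
              drop = FALSE]

  members <- root
  frontier <- root
  depth <- 0
  while (length(frontier) > 0 && depth < policy$max_depth) {
    nxt <- setdiff(unique(edges$object[edges$subject %in% frontier]), members)
    members <- c(members, nxt)
    frontier <- nxt
    depth <- depth + 1
  }

  keep_always <- c(RDF_TYPE, bp3("displayName"))
  keep <- tr$subject %in% members &
    (tr$predicate %in% keep_always |
       (tr$predicate %in% follow &
          (tr$object_is_literal | tr$object %in% members)))
  sub <- biopax_graph(tr[keep, , drop = FALSE],
                      namespaces = graph$namespaces,
                      check_vocabulary = FALSE)
  sub$root <- root
  sub$member_nodes <- sort(members)
  class(sub) <- c("biopax_subgraph", class(sub))
  sub
}

#' View filter: class whitelist plus property blacklist
#'
#' @param keep_classes BioPAX classes (local names or IRIs) whose instances
#'   survive the view.
#' @param drop_properties Properties whose triples are removed.
#' @return An object of class `view_filter`.
#' @seealso [simplified_view_filter()] for the shipped preset.
#' @export
view_filter <- function(keep_classes, drop_properties = character()) {
  classes <- bp3_local(keep_classes)
  props <- bp3_local(drop_properties)
  bad_cls <- setdiff(classes, .biopax_class_table()$class)
  if (length(bad_cls) > 0) {
    abort(paste0("Not a BioPAX class: ", paste(bad_cls, collapse = ", ")))
  }
  bad_prop <- setdiff(props, .biopax_property_names)
  if (length(bad_prop) > 0) {
    abort(paste0("Not a BioPAX property: ", paste(bad_prop, collapse = ", ")))
  }
  structure(list(keep_classes = classes, drop_properties = props),
            class = "view_filter")
}

#' The shipped simplified-view preset
#'
#' Keeps the nine structural classes of a pathway drawing (Pathway,
#' PathwayStep, BiochemicalReaction, Complex, Protein, SmallMolecule,
#' Stoichiometry, Catalysis, Control) and drops the ten annotation-heavy
#' properties that dominate raw exports (`dataSource`, `comment`, `xref`,
#' `controlType`, `conversionDirection`, `evidence`, `organism`,
#' `availability`, `entityReference`, `cellularLocation`).
#'
#' @return A [view_filter()].
#' @export
simplified_view_filter <- function() {
  view_filter(
    keep_classes = c("Pathway", "PathwayStep", "BiochemicalReaction",
                     "Complex", "Protein", "SmallMolecule", "Stoichiometry",
                     "Catalysis", "Control"),
    drop_properties = c("dataSource", "comment", "xref", "controlType",
                        "conversionDirection", "evidence", "organism",
                        "availability", "entityReference", "cellularLocation")
  )
}

#' Apply a view filter to a graph
#'
#' Keeps only the nodes whose `rdf:type` is whitelisted, then the triples
#' whose predicate is not blacklisted and whose IRI endpoints are both kept
#' nodes. `rdf:type` triples and literal-valued triples of kept nodes
#' survive regardless of the object test. Idempotent.
#'
#' @param graph A [biopax_graph()].
#' @param filter A [view_filter()].
#' @return A `biopax_subgraph` with `member_nodes` set to the kept nodes.
#' @export
filter_view <- function(graph, filter = simplified_view_filter()) {
  tr <- graph$triples
  kept_nodes <- sort(unique(unlist(
    lapply(filter$keep_classes, function(cl) instances_of(graph, cl))
  )))
  drop <- bp3(filter$drop_properties)
  keep <- tr$subject %in% kept_nodes &
    !tr$predicate %in% drop &
    (tr$predicate == RDF_TYPE | tr$object_is_literal |
       tr$object %in% kept_nodes)
  sub <- biopax_graph(tr[keep, , drop = FALSE],
                      namespaces = graph$namespaces,
                      check_vocabulary = FALSE)
  sub$root <- NA_character_
  sub$member_nodes <- kept_nodes
  class(sub) <- c("biopax_subgraph", class(sub))
  sub
}
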