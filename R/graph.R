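#' Build a tidy RDF triple table
#'
#' Constructs the triple tibble underlying a [biopax_graph()]. Every row is
#' one RDF statement; IRI objects and literal objects live in the same
#' `object` column and are told apart by `object_is_literal`.
#'
#' @param subject,predicate Character vectors of absolute IRIs.
#' @param object Character vector: IRIs or literal text.
#' @param object_is_literal Logical vector, `TRUE` where `object` is a
#'   literal. Default all `FALSE`.
#' @param datatype Optional datatype IRIs for literal objects (`NA` for
#'   plain literals and all IRI objects).
#' @param lang Optional language tags. Preserved on round-trip but ignored
#'   when comparing triples.
#' @return A tibble with columns `subject`, `predicate`, `object`,
#'   `object_is_literal`, `datatype`, `lang`.
#' @export
rdf_triples <- function(subject, predicate, object,
                        object_is_literal = FALSE,
                        datatype = NA_character_,
                        lang = NA_character_) {
  tibble::tibble(
    subject = as.character(subject),
    predicate = as.character(predicate),
    object = as.character(object),
    object_is_literal = rep_len(as.logical(object_is_literal), length(subject)),
    datatype = rep_len(as.character(datatype), length(subject)),
    lang = rep_len(as.character(lang), length(subject))
  )
}

.empty_triples <- function() {
  rdf_triples(character(), character(), character(), logical(),
              character(), character())
}

# Canonical ordering + deduplication. Language tags do not participate in
# triple identity; datatypes do.
.canonical_triples <- function(triples) {
  triples <- triples[!duplicated(triples[c("subject", "predicate", "object",
                                           "object_is_literal", "datatype")]), ,
                     drop = FALSE]
  ord <- order(triples$subject, triples$predicate, triples$object,
               triples$object_is_literal, method = "radix")
  tibble::as_tibble(triples[ord, , drop = FALSE])
}

#' A BioPAX Level 3 graph as a set of RDF triples
#'
#' The low-level representation every other operation in the package works
#' on: a deduplicated set of (subject, predicate, object) statements plus a
#' prefix-to-IRI namespace table that always contains `bp3`.
#'
#' @param triples A triple tibble as produced by [rdf_triples()].
#' @param namespaces Named character vector mapping prefixes to namespace
#'   IRIs; merged over the defaults (`bp3`, `rdf`, `xsd`, `owl`).
#' @param check_vocabulary Validate that every bp3-prefixed predicate is in
#'   the shipped vocabulary? Default `TRUE`; [read_biopax()] downgrades this
#'   to a warning because real database exports use more of the ontology
#'   than the subset this toolkit reasons over.
#' @return An object of class `biopax_graph`: a list with elements `triples`
#'   and `namespaces`.
#' @seealso [read_biopax()], [instances_of()], [n_triples()]
#' @export
biopax_graph <- function(triples = .empty_triples(),
                         namespaces = character(),
                         check_vocabulary = TRUE) {
  stopifnot(is.data.frame(triples))
  need <- c("subject", "predicate", "object", "object_is_literal",
            "datatype", "lang")
  missing_cols <- setdiff(need, names(triples))
  if (length(missing_cols) > 0) {
    abort(paste0("Triple table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ns <- DEFAULT_NAMESPACES
  if (length(namespaces) > 0) {
    ns[names(namespaces)] <- unname(namespaces)
  }
  g <- structure(
    list(triples = .canonical_triples(triples[need]), namespaces = ns),
    class = "biopax_graph"
  )
  if (check_vocabulary) validate_biopax_graph(g)
  g
}

#' Validate the structural invariants of a BioPAX graph
#'
#' Checks that subjects and predicates are IRI-shaped (contain a scheme
#' separator), that there are no duplicate triples, and that every
#' bp3-prefixed predicate is part of the shipped vocabulary.
#'
#' @param graph A [biopax_graph()].
#' @param on_unknown_predicate `"error"` (default) or `"warn"` for bp3
#'   predicates outside the vocabulary table.
#' @return `graph`, invisibly. Errors (or warns) on violation.
#' @export
validate_biopax_graph <- function(graph, on_unknown_predicate = "error") {
  tr <- graph$triples
  bad_iri <- c(
    tr$subject[!grepl(":", tr$subject, fixed = TRUE)],
    tr$predicate[!grepl(":", tr$predicate, fixed = TRUE)]
  )
  if (length(bad_iri) > 0) {
    abort(paste0("Not an absolute IRI: ", bad_iri[1]))
  }
  if (!"bp3" %in% names(graph$namespaces) ||
      graph$namespaces[["bp3"]] != BP3_NS) {
    abort("Namespace table must map 'bp3' to the BioPAX Level 3 namespace")
  }
  voc <- c(biopax_vocabulary()$properties$iri, RDF_TYPE)
  bp3_preds <- unique(tr$predicate[startsWith(tr$predicate, BP3_NS)])
  unknown <- setdiff(bp3_preds, voc)
  if (length(unknown) > 0) {
    msg <- paste0("bp3 predicate(s) outside the shipped vocabulary: ",
                  paste(bp3_local(unknown), collapse = ", "))
    if (identical(on_unknown_predicate, "warn")) warn(msg) else abort(msg)
  }
  invisible(graph)
}

#' @export
print.biopax_graph <- function(x, ...) {
  cat("<biopax_graph> ", n_triples(x), " triples, ",
      length(unique(x$triples$subject)), " subjects\n", sep = "")
  cat("namespaces: ", paste0(names(x$namespaces), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Number of triples in a graph
#' @param graph A [biopax_graph()].
#' @return Integer count.
#' @export
n_triples <- function(graph) nrow(graph$triples)

#' Extract the triple table of a graph
#' @param graph A [biopax_graph()] or pathway subgraph.
#' @return The triple tibble.
#' @export
triples <- function(graph) graph$triples

# TRUE when two graphs contain the same statement set (language tags and
# row order ignored).
#' Compare two graphs as triple sets
#' @param a,b Graphs or triple tibbles.
#' @return `TRUE` if the statement sets are equal.
#' @export
same_triples <- function(a, b) {
  key <- function(g) {
    tr <- if (is.data.frame(g)) g else g$triples
    sort(paste(tr$subject, tr$predicate, tr$object, tr$object_is_literal,
               ifelse(is.na(tr$datatype), "", tr$datatype), sep = "\r"))
  }
  identical(key(a), key(b))
}

#' Instances of a BioPAX class in a graph
#'
#' Returns the subjects declared (via `rdf:type`) to be instances of a
#' class, optionally including its descendants in the shipped hierarchy
#' (e.g. `Interaction` with subclasses covers `BiochemicalReaction` and
#' `Catalysis`).
#'
#' @param graph A [biopax_graph()].
#' @param class_name Local BioPAX class name or full IRI.
#' @param include_subclasses Also count instances of descendant classes?
#'   Default `FALSE`.
#' @return Character vector of instance IRIs (sorted, unique).
#' @examples
#' g <- rna_pol2_fixture()
#' instances_of(g, "Interaction", include_subclasses = TRUE)
#' @export
instances_of <- function(graph, class_name, include_subclasses = FALSE) {
  local <- bp3_local(class_name)
  tab <- .biopax_class_table()
  if (!local %in% tab$class) {
    abort(paste0("Unknown BioPAX class: ", class_name))
  }
  wanted <- if (include_subclasses) biopax_descendants(local) else local
  tr <- graph$triples
  hit <- tr$predicate == RDF_TYPE & !tr$object_is_literal &
    tr$object %in% bp3(wanted)
  sort(unique(tr$subject[hit]))
}

# Objects of (subject, predicate) pairs, IRI objects only.
.objects_of <- function(triples, subjects, predicate_iri) {
  hit <- triples$subject %in% subjects &
    triples$predicate == predicate_iri & !triples$object_is_literal
  unique(triples$object[hit])
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.biopax_graph <- function(x, ...) x$triples

#' @export
glance.biopax_graph <- function(x, ...) {
  tr <- x$triples
  tibble::tibble(
    n_triples = nrow(tr),
    n_subjects = length(unique(tr$subject)),
    n_typed_instances = length(unique(tr$subject[tr$predicate == RDF_TYPE])),
    n_literals = sum(tr$object_is_literal)
  )
}
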