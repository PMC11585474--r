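# Cross-reference mapping audit: classify every Protein / SmallMolecule as
# mapped to its reference knowledgebase (UniProtKB / ChEBI), lacking an
# entity reference, or carrying a reference that never reaches the target
# database. The three outcomes partition the entity set.

#' Database-name matching policy for cross-reference audits
#'
#' Pathway databases spell the same target database differently in their
#' `bp3:db` literals (Reactome's standalone export writes `"UniProt"` and
#' `"ChEBI"` where other exports write `"uniprot"` and `"chebi"`), so the
#' audit matches against a configurable synonym set, case-insensitively by
#' default.
#'
#' @param target_db Display name of the target database (e.g.
#'   `"UniProtKB"`).
#' @param synonyms Character vector of accepted `bp3:db` strings.
#' @param case_insensitive Match ignoring case? Default `TRUE`.
#' @return An object of class `db_name_policy`.
#' @examples
#' uniprot_policy()
#' chebi_policy()
#' @export
db_name_policy <- function(target_db, synonyms, case_insensitive = TRUE) {
  stopifnot(is.character(synonyms), length(synonyms) > 0)
  structure(
    list(target_db = target_db, synonyms = synonyms,
         case_insensitive = isTRUE(case_insensitive)),
    class = "db_name_policy"
  )
}

#' @rdname db_name_policy
#' @export
uniprot_policy <- function() {
  db_name_policy("UniProtKB",
                 c("UniProt", "uniprot", "UniProtKB", "uniprot knowledgebase"))
}

#' @rdname db_name_policy
#' @export
chebi_policy <- function() {
  db_name_policy("ChEBI", c("ChEBI", "chebi"))
}

#' Read a database-name policy from a YAML or JSON config block
#'
#' The block must provide `target_db` and `synonyms`; `case_insensitive`
#' defaults to true.
#'
#' @param path Path to a YAML (or JSON — valid YAML) file.
#' @return A [db_name_policy()].
#' @export
read_db_name_policy <- function(path) {
  cfg <- yaml::read_yaml(path)
  db_name_policy(
    target_db = cfg$target_db %||% "custom",
    synonyms = unlist(cfg$synonyms),
    case_insensitive = cfg$case_insensitive %||% TRUE
  )
}

.db_matches <- function(db_values, policy) {
  syn <- policy$synonyms
  if (policy$case_insensitive) {
    tolower(db_values) %in% tolower(syn)
  } else {
    db_values %in% syn
  }
}

# Transitive closure over bp3:memberEntityReference from a reference set,
# with cycle protection. Used for family/ortholog-based exports whose
# generic references only reach the target database through their members.
.member_closure <- function(triples, refs) {
  member <- bp3("memberEntityReference")
  seen <- refs
  frontier <- refs
  while (length(frontier) > 0) {
    nxt <- setdiff(.objects_of(triples, frontier, member), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Audit entity-to-database cross-reference mappings
#'
#' Classifies every instance of `entity_class` into exactly one of three
#' outcomes. An entity is *mapped* when a path
#' entity --`bp3:entityReference`--> reference
#' (--`bp3:memberEntityReference`-->, transitively, when `follow_members`)
#' --`bp3:xref`--> UnificationXref exists whose `bp3:db` literal matches the
#' policy; its `bp3:id` literals are collected. It is *no-reference* when it
#' has no `bp3:entityReference` triple at all, and
#' *reference-without-target* otherwise. Only UnificationXref instances
#' assert identity; relationship and publication xrefs are ignored.
#'
#' @param graph A [biopax_graph()].
#' @param entity_class `"Protein"` or `"SmallMolecule"` (local name or
#'   IRI).
#' @param policy A [db_name_policy()].
#' @param follow_members Traverse `bp3:memberEntityReference` transitively?
#'   Default `FALSE`.
#' @return An object of class `mapping_audit`: counts (`n_entities`,
#'   `n_mapped`, `n_unique_ids`, `n_no_reference`, `n_reference_no_target`),
#'   the per-entity classification (`entities` tibble with `entity`,
#'   `status`) and the mapped pairs (`mapped_pairs` tibble with `entity`,
#'   `id`).
#' @seealso [audit_protein_uniprot()], [audit_smallmolecule_chebi()]
#' @export
audit_mappings <- function(graph, entity_class, policy,
                           follow_members = FALSE) {
  local <- bp3_local(entity_class)
  if (!local %in% c("Protein", "SmallMolecule")) {
    abort(paste0("Unsupported entity class for mapping audit: ", entity_class))
  }
  tr <- graph$triples
  entities <- instances_of(graph, local)
  ref_pred <- bp3("entityReference")
  xref_pred <- bp3("xref")
  db_pred <- bp3("db")
  id_pred <- bp3("id")
  unif <- instances_of(graph, "UnificationXref")

  # xrefs that reach the target database, and their ids
  xref_db <- tr[tr$predicate == db_pred & tr$object_is_literal &
                  tr$subject %in% unif, c("subject", "object")]
  target_xrefs <- unique(xref_db$subject[.db_matches(xref_db$object, policy)])
  xref_ids <- tr[tr$predicate == id_pred & tr$object_is_literal &
                   tr$subject %in% target_xrefs, c("subject", "object")]

  status <- character(length(entities))
  pairs_entity <- character()
  pairs_id <- character()
  for (i in seq_along(entities)) {
    refs <- .objects_of(tr, entities[i], ref_pred)
    if (length(refs) == 0) {
      status[i] <- "no_reference"
      next
    }
    if (follow_members) refs <- .member_closure(tr, refs)
    xr <- intersect(.objects_of(tr, refs, xref_pred), target_xrefs)
    if (length(xr) == 0) {
      status[i] <- "reference_no_target"
    } else {
      status[i] <- "mapped"
      ids <- unique(xref_ids$object[xref_ids$subject %in% xr])
      pairs_entity <- c(pairs_entity, rep(entities[i], length(ids)))
      pairs_id <- c(pairs_id, ids)
    }
  }

  counts <- table(factor(status, levels = c("mapped", "no_reference",
                                            "reference_no_target")))
  out <- structure(
    list(
      entity_class = local,
      target_db = policy$target_db,
      follow_members = follow_members,
      n_entities = length(entities),
      n_mapped = unname(counts[["mapped"]]),
      n_unique_ids = length(unique(pairs_id)),
      n_no_reference = unname(counts[["no_reference"]]),
      n_reference_no_target = unname(counts[["reference_no_target"]]),
      entities = tibble::tibble(entity = entities, status = status),
      mapped_pairs = tibble::tibble(entity = pairs_entity, id = pairs_id)
    ),
    class = "mapping_audit"
  )
  # partition invariant, asserted on every run
  stopifnot(out$n_mapped + out$n_no_reference + out$n_reference_no_target ==
              out$n_entities)
  out
}

#' Audit Protein-to-UniProtKB mappings
#'
#' @inheritParams audit_mappings
#' @param policy A [db_name_policy()]; defaults to [uniprot_policy()].
#' @return A `mapping_audit` object; see [audit_mappings()].
#' @export
audit_protein_uniprot <- function(graph, policy = uniprot_policy(),
                                  follow_members = FALSE) {
  audit_mappings(graph, "Protein", policy, follow_members)
}

#' Audit SmallMolecule-to-ChEBI mappings
#'
#' @inheritParams audit_mappings
#' @param policy A [db_name_policy()]; defaults to [chebi_policy()].
#' @return A `mapping_audit` object; see [audit_mappings()].
#' @export
audit_smallmolecule_chebi <- function(graph, policy = chebi_policy(),
                                      follow_members = FALSE) {
  audit_mappings(graph, "SmallMolecule", policy, follow_members)
}

#' @export
print.mapping_audit <- function(x, ...) {
  cat("<mapping_audit> ", x$entity_class, " -> ", x$target_db,
      if (x$follow_members) " (following member references)", "\n", sep = "")
  cat("  entities:             ", x$n_entities, "\n", sep = "")
  cat("  mapped:               ", x$n_mapped,
      " (", x$n_unique_ids, " unique ids)\n", sep = "")
  cat("  no reference:         ", x$n_no_reference, "\n", sep = "")
  cat("  reference, no target: ", x$n_reference_no_target, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mapping_audit <- function(x, ...) {
  ids <- x$mapped_pairs |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(ids = paste(sort(.data$id), collapse = ";"),
                     .groups = "drop")
  dplyr::left_join(x$entities, ids, by = "entity")
}

#' @export
glance.mapping_audit <- function(x, ...) {
  tibble::tibble(
    entity_class = x$entity_class,
    target_db = x$target_db,
    n_entities = x$n_entities,
    n_mapped = x$n_mapped,
    n_unique_ids = x$n_unique_ids,
    n_no_reference = x$n_no_reference,
    n_reference_no_target = x$n_reference_no_target
  )
}

#' Write a mapping-audit report as TSV
#'
#' One row with the partition counts (the bottom-panel columns of the
#' database comparison), optionally followed by a per-entity mapping table.
#'
#' @param audit A `mapping_audit` object.
#' @param path Output TSV path.
#' @param per_entity Also write `<path>.entities.tsv` with one row per
#'   entity? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(audit, path, per_entity = FALSE) {
  utils::write.table(glance(audit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (per_entity) {
    utils::write.table(tidy(audit), paste0(path, ".entities.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
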