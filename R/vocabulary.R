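#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr filter mutate select distinct arrange group_by ungroup
#'   summarise left_join anti_join semi_join bind_rows n pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_lgl map2
NULL

# Core namespaces. bp3 is fixed by the BioPAX Level 3 ontology; abs is the
# namespace under which derived abstraction predicates are minted.
BP3_NS <- "http://www.biopax.org/release/biopax-level3.owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
ABS_NS <- "http://abstraction/"
RDF_TYPE <- paste0(RDF_NS, "type")

DEFAULT_NAMESPACES <- c(
  bp3 = BP3_NS,
  rdf = RDF_NS,
  xsd = XSD_NS,
  owl = OWL_NS
)

#' Build a BioPAX Level 3 IRI from a local name
#'
#' Prefixes `x` with the canonical BioPAX Level 3 namespace
#' `http://www.biopax.org/release/biopax-level3.owl#`. Vectorised.
#'
#' @param x Character vector of local names (e.g. `"Protein"`,
#'   `"pathwayComponent"`).
#' @return Character vector of absolute IRIs.
#' @examples
#' bp3("Protein")
#' @export
bp3 <- function(x) paste0(BP3_NS, x)

#' Strip the BioPAX namespace from an IRI, if present
#' @param iri Character vector of IRIs.
#' @return Local names where the IRI is in the bp3 namespace, the input
#'   otherwise.
#' @export
bp3_local <- function(iri) {
  ifelse(startsWith(iri, BP3_NS), substring(iri, nchar(BP3_NS) + 1L), iri)
}

# Class hierarchy of the BioPAX Level 3 subset this toolkit reasons over.
# Entity roots the entity classes; utility classes (PathwayStep, Stoichiometry,
# EntityReference, Xref, Provenance) root their own trees, so the table is a
# forest. Shipped as static data: behaviour must be deterministic without
# fetching the ontology OWL.
.biopax_class_table <- function() {
  tibble::tribble(
    ~class,                   ~parent,
    "Entity",                 NA_character_,
    "PhysicalEntity",         "Entity",
    "Protein",                "PhysicalEntity",
    "SmallMolecule",          "PhysicalEntity",
    "Complex",                "PhysicalEntity",
    "Dna",                    "PhysicalEntity",
    "Rna",                    "PhysicalEntity",
    "Interaction",            "Entity",
    "Conversion",             "Interaction",
    "BiochemicalReaction",    "Conversion",
    "Control",                "Interaction",
    "Catalysis",              "Control",
    "Pathway",                "Entity",
    "PathwayStep",            NA_character_,
    "Stoichiometry",          NA_character_,
    "EntityReference",        NA_character_,
    "ProteinReference",       "EntityReference",
    "SmallMoleculeReference", "EntityReference",
    "Xref",                   NA_character_,
    "UnificationXref",        "Xref",
    "RelationshipXref",       "Xref",
    "PublicationXref",        "Xref",
    "Provenance",             NA_character_
  )
}

.biopax_property_names <- c(
  "pathwayComponent", "pathwayOrder", "nextStep", "stepProcess",
  "left", "right", "controller", "controlled", "component",
  "entityReference", "memberEntityReference", "xref", "db", "id",
  "dataSource", "comment", "evidence", "organism", "availability",
  "cellularLocation", "conversionDirection", "controlType", "displayName",
  "stepConversion", "participantStoichiometry", "stoichiometricCoefficient",
  "physicalEntity"
)

#' The BioPAX Level 3 vocabulary used by this toolkit
#'
#' Returns the static class hierarchy and property list the package reasons
#' over. The class table is a forest: entity classes are rooted at `Entity`
#' (with `Protein`, `SmallMolecule`, `Complex`, `Dna` and `Rna` descending
#' from `PhysicalEntity`, and `BiochemicalReaction`/`Catalysis` descending
#' from `Interaction`), while utility classes such as `PathwayStep`,
#' `EntityReference` and `Xref` root their own trees.
#'
#' @return A list with elements `classes` (tibble with columns `class`,
#'   `parent`, `iri`) and `properties` (tibble with columns `property`,
#'   `iri`).
#' @examples
#' biopax_vocabulary()$classes
#' @export
biopax_vocabulary <- function() {
  cls <- .biopax_class_table()
  cls$iri <- bp3(cls$class)
  list(
    classes = cls,
    properties = tibble::tibble(
      property = .biopax_property_names,
      iri = bp3(.biopax_property_names)
    )
  )
}

#' Descendant classes in the BioPAX hierarchy
#'
#' @param class_name Local class name (e.g. `"Interaction"`).
#' @param include_self Include `class_name` itself? Default `TRUE`.
#' @return Character vector of local class names.
#' @examples
#' biopax_descendants("Interaction")
#' @export
biopax_descendants <- function(class_name, include_self = TRUE) {
  tab <- .biopax_class_table()
  if (!class_name %in% tab$class) {
    abort(paste0("Unknown BioPAX class: ", class_name))
  }
  out <- class_name
  frontier <- class_name
  while (length(frontier) > 0) {
    kids <- tab$class[!is.na(tab$parent) & tab$parent %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  if (!include_self) out <- setdiff(out, class_name)
  out
}
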