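# Hand-built miniature graphs used across test files.

EXN <- "http://biopax.example/test#"
exn <- function(x) paste0(EXN, x)

# three proteins: one mapped to UniProtKB, one without any entity
# reference, one whose reference only carries a PubMed xref
three_protein_fixture <- function() {
  tr <- dplyr::bind_rows(
    rdf_triples(exn(c("P1", "P2", "P3")), O_TYPE, obp("Protein")),
    rdf_triples(exn(c("PR1", "PR3")), O_TYPE, obp("ProteinReference")),
    rdf_triples(exn(c("X1", "X3")), O_TYPE, obp("UnificationXref")),
    rdf_triples(exn("P1"), obp("entityReference"), exn("PR1")),
    rdf_triples(exn("P3"), obp("entityReference"), exn("PR3")),
    rdf_triples(exn("PR1"), obp("xref"), exn("X1")),
    rdf_triples(exn("PR3"), obp("xref"), exn("X3")),
    rdf_triples(exn("X1"), obp("db"), "UniProt", object_is_literal = TRUE),
    rdf_triples(exn("X1"), obp("id"), "P00533", object_is_literal = TRUE),
    rdf_triples(exn("X3"), obp("db"), "pubmed", object_is_literal = TRUE),
    rdf_triples(exn("X3"), obp("id"), "123456", object_is_literal = TRUE)
  )
  biopax_graph(tr, namespaces = c(ex = EXN))
}

# family/ortholog style: the protein's direct reference has no UniProtKB
# xref, but a (possibly nested) member reference does
member_reference_fixture <- function(depth = 1, cycle = FALSE) {
  refs <- exn(paste0("FR", seq_len(depth + 1)))
  tr <- dplyr::bind_rows(
    rdf_triples(exn("P1"), O_TYPE, obp("Protein")),
    rdf_triples(refs, O_TYPE, obp("ProteinReference")),
    rdf_triples(exn("X1"), O_TYPE, obp("UnificationXref")),
    rdf_triples(exn("P1"), obp("entityReference"), refs[1]),
    rdf_triples(refs[-length(refs)], obp("memberEntityReference"), refs[-1]),
    rdf_triples(refs[length(refs)], obp("xref"), exn("X1")),
    rdf_triples(exn("X1"), obp("db"), "uniprot", object_is_literal = TRUE),
    rdf_triples(exn("X1"), obp("id"), "Q9Y6K9", object_is_literal = TRUE)
  )
  if (cycle) {
    tr <- dplyr::bind_rows(
      tr,
      rdf_triples(refs[length(refs)], obp("memberEntityReference"), refs[1])
    )
  }
  biopax_graph(tr, namespaces = c(ex = EXN))
}

# small random corpora for property tests: varied structure, small sizes
random_spec <- function(seed) {
  synth_spec(
    n_root_pathways = 1 + seed %% 2,
    subpathways_per_root = seed %% 3,
    chain_length = 3 + seed %% 4,
    reactions_per_step = 1 + seed %% 2,
    control_step_fraction = (seed %% 3) / 6,
    n_proteins = 8 + seed %% 5,
    n_small_molecules = 6 + seed %% 4,
    frac_no_reference = 0.2,
    frac_reference_no_target = 0.1,
    shared_reference_fraction = (seed %% 4) / 8,
    seed = seed
  )
}
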