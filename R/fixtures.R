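# Synthetic BioPAX corpora with exact ground truth, plus the hand-coded
# RNA Pol II elongation worked example. The generator's purpose is
# structural coverage of the features under audit and abstraction —
# pathway hierarchies, step chains, control-only steps, mapping defects —
# not statistical realism of real pathway topology.

FIXTURE_NS <- "http://biopax.example/corpus#"
REACTOME_FIXTURE_NS <- "http://biopax.example/reactome#"

.ex <- function(x, ns = FIXTURE_NS) paste0(ns, x)

#' Specification for a synthetic BioPAX corpus
#'
#' Describes the structure and defect rates of a generated corpus. The
#' defaults describe a small but fully featured corpus: one root pathway
#' with two sub-pathways and a five-step chain, 50 proteins and 30 small
#' molecules with 20% of entities lacking an entity reference and 10%
#' carrying a reference that never reaches the target database, and the
#' two db-string dialects observed across database exports.
#'
#' @param n_root_pathways Number of root pathways.
#' @param subpathways_per_root Sub-pathways per root (each carries its own
#'   two-step internal chain).
#' @param chain_length Steps in each root's `bp3:nextStep` chain.
#' @param reactions_per_step Reactions attached to every reaction-bearing
#'   step (>= 1).
#' @param control_step_fraction Fraction of root-chain steps that carry only
#'   a control process (a Catalysis) and no reaction.
#' @param n_proteins,n_small_molecules Entity counts.
#' @param frac_no_reference Fraction of entities (per class) with no
#'   `bp3:entityReference` triple.
#' @param frac_reference_no_target Fraction of entities whose reference
#'   only reaches a non-target xref (a PubMed unification xref).
#' @param db_dialects Named list with elements `uniprot` and `chebi`: the
#'   `bp3:db` strings cycled through when minting target xrefs.
#' @param shared_reference_fraction Fraction of mapped entities that reuse
#'   the first mapped entity's reference instead of minting their own
#'   (different molecular states of the same molecule), driving the
#'   unique-identifier count below the mapping count.
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `synth_spec`.
#' @seealso [generate_corpus()]
#' @export
synth_spec <- function(n_root_pathways = 1,
                       subpathways_per_root = 2,
                       chain_length = 5,
                       reactions_per_step = 1,
                       control_step_fraction = 0.2,
                       n_proteins = 50,
                       n_small_molecules = 30,
                       frac_no_reference = 0.2,
                       frac_reference_no_target = 0.1,
                       db_dialects = list(uniprot = c("UniProt", "uniprot"),
                                          chebi = c("ChEBI", "chebi")),
                       shared_reference_fraction = 0.2,
                       seed = 1L) {
  spec <- list(
    n_root_pathways = as.integer(n_root_pathways),
    subpathways_per_root = as.integer(subpathways_per_root),
    chain_length = as.integer(chain_length),
    reactions_per_step = as.integer(reactions_per_step),
    control_step_fraction = control_step_fraction,
    n_proteins = as.integer(n_proteins),
    n_small_molecules = as.integer(n_small_molecules),
    frac_no_reference = frac_no_reference,
    frac_reference_no_target = frac_reference_no_target,
    db_dialects = db_dialects,
    shared_reference_fraction = shared_reference_fraction,
    seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(
      n_root_pathways >= 0, subpathways_per_root >= 0, chain_length >= 1,
      reactions_per_step >= 1, n_proteins >= 0, n_small_molecules >= 0,
      control_step_fraction >= 0, control_step_fraction <= 1,
      frac_no_reference >= 0, frac_reference_no_target >= 0,
      shared_reference_fraction >= 0, shared_reference_fraction <= 1,
      is.character(db_dialects$uniprot), is.character(db_dialects$chebi)
    )
  })
  if (spec$frac_no_reference + spec$frac_reference_no_target > 1) {
    abort("frac_no_reference + frac_reference_no_target must be <= 1")
  }
  structure(spec, class = "synth_spec")
}

# mutable triple accumulator
.new_acc <- function() {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  acc
}

.acc_add <- function(acc, s, p, o, lit = FALSE, dt = NA_character_) {
  acc$rows[[length(acc$rows) + 1L]] <-
    rdf_triples(s, p, o, object_is_literal = lit, datatype = dt)
}

.acc_instance <- function(acc, iri, class_name, label = NULL) {
  .acc_add(acc, iri, RDF_TYPE, bp3(class_name))
  if (!is.null(label)) {
    .acc_add(acc, iri, bp3("displayName"), label, lit = TRUE)
  }
  iri
}

# Entity wiring for one entity class: allocates mapping-defect quotas by
# deterministic floors, assigns them to seeded-shuffled entity indices,
# mints references and xrefs, and returns the exact audit partition.
.generate_entities <- function(acc, class_name, ref_class, n, spec,
                               dialects, id_fmt) {
  if (n == 0) {
    return(list(n_entities = 0L, n_mapped = 0L, n_unique_ids = 0L,
                n_no_reference = 0L, n_reference_no_target = 0L))
  }
  tag <- if (class_name == "Protein") "Protein" else "SmallMolecule"
  entities <- vapply(seq_len(n), function(i)
    .acc_instance(acc, .ex(sprintf("%s_%d", tag, i)), class_name,
                  sprintf("%s %d", tag, i)), "")

  n_noref <- floor(spec$frac_no_reference * n)
  n_refnt <- floor(spec$frac_reference_no_target * n)
  n_mapped <- n - n_noref - n_refnt
  shuffled <- sample.int(n)
  idx_noref <- shuffled[seq_len(n_noref)]
  idx_refnt <- shuffled[n_noref + seq_len(n_refnt)]
  idx_mapped <- shuffled[n_noref + n_refnt + seq_len(n_mapped)]

  for (k in seq_along(idx_refnt)) {
    e <- entities[idx_refnt[k]]
    ref <- .acc_instance(acc, paste0(e, "_ref"), ref_class)
    xr <- .acc_instance(acc, paste0(e, "_pubmed"), "UnificationXref")
    .acc_add(acc, e, bp3("entityReference"), ref)
    .acc_add(acc, ref, bp3("xref"), xr)
    .acc_add(acc, xr, bp3("db"), "pubmed", lit = TRUE)
    .acc_add(acc, xr, bp3("id"), as.character(10000 + k), lit = TRUE)
  }

  n_shared <- 0L
  if (n_mapped >= 2) {
    n_shared <- min(floor(spec$shared_reference_fraction * n_mapped),
                    n_mapped - 1L)
  }
  n_own <- n_mapped - n_shared
  first_ref <- NULL
  for (k in seq_len(n_mapped)) {
    e <- entities[idx_mapped[k]]
    if (k <= n_own) {
      ref <- .acc_instance(acc, paste0(e, "_ref"), ref_class)
      xr <- .acc_instance(acc, paste0(e, "_xref"), "UnificationXref")
      .acc_add(acc, ref, bp3("xref"), xr)
      .acc_add(acc, xr, bp3("db"), dialects[(k - 1L) %% length(dialects) + 1L],
               lit = TRUE)
      .acc_add(acc, xr, bp3("id"), sprintf(id_fmt, k), lit = TRUE)
      if (k == 1L) first_ref <- ref
    } else {
      ref <- first_ref  # shared reference: same molecule, other state
    }
    .acc_add(acc, e, bp3("entityReference"), ref)
  }

  list(n_entities = as.integer(n),
       n_mapped = as.integer(n_mapped),
       n_unique_ids = as.integer(n_own),
       n_no_reference = as.integer(n_noref),
       n_reference_no_target = as.integer(n_refnt),
       entities = entities)
}

#' Generate a synthetic BioPAX corpus with known ground truth
#'
#' Emits a [biopax_graph()] realizing a [synth_spec()] exactly — pathway
#' hierarchies via `bp3:pathwayComponent`, root step chains via
#' `bp3:pathwayOrder` + `bp3:nextStep`, reactions and catalyses grouped by
#' `bp3:stepProcess`, reaction participants via `bp3:left`/`bp3:right`, and
#' entities wired to references and unification xrefs with the configured
#' db-string dialects. The ground truth (census, audit partitions per
#' entity class, derived abstraction edges per root) is computed during
#' construction, not by re-analyzing the emitted graph, so it is an
#' independent yardstick for every analysis module.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `graph` (the corpus), `truth` (list with
#'   `census`, `audit`, `abstract_edges`, `roots`) and `spec`.
#' @examples
#' corpus <- generate_corpus(synth_spec(chain_length = 3, seed = 7))
#' corpus$truth$audit$Protein
#' @export
generate_corpus <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, .generate_corpus_impl(spec))
}

.generate_corpus_impl <- function(spec) {
  acc <- .new_acc()
  counts <- c(BiochemicalReaction = 0L, PathwayStep = 0L, Pathway = 0L,
              Interaction = 0L, SmallMolecule = 0L, Protein = 0L,
              Dna = 0L, Rna = 0L)
  roots <- character()
  abstract_edges <- list()

  audit_p <- .generate_entities(
    acc, "Protein", "ProteinReference", spec$n_proteins, spec,
    spec$db_dialects$uniprot, "P%05d")
  counts[["Protein"]] <- spec$n_proteins
  audit_sm <- .generate_entities(
    acc, "SmallMolecule", "SmallMoleculeReference", spec$n_small_molecules,
    spec, spec$db_dialects$chebi, "CHEBI:%d")
  counts[["SmallMolecule"]] <- spec$n_small_molecules
  participants <- c(audit_p$entities %||% character(),
                    audit_sm$entities %||% character())

  for (r in seq_len(spec$n_root_pathways)) {
    root <- .acc_instance(acc, .ex(sprintf("Pathway_r%d", r)), "Pathway",
                          sprintf("Synthetic root pathway %d", r))
    counts[["Pathway"]] <- counts[["Pathway"]] + 1L
    roots <- c(roots, root)

    # sub-pathways, each with a two-step internal chain
    sub_iris <- character()
    sub_entry_rxn <- character()
    for (j in seq_len(spec$subpathways_per_root)) {
      sp <- .acc_instance(acc, .ex(sprintf("Pathway_r%d_s%d", r, j)),
                          "Pathway", sprintf("Sub-pathway %d.%d", r, j))
      counts[["Pathway"]] <- counts[["Pathway"]] + 1L
      .acc_add(acc, root, bp3("pathwayComponent"), sp)
      sub_iris <- c(sub_iris, sp)
      prev_step <- NULL
      for (t in 1:2) {
        st <- .acc_instance(acc, .ex(sprintf("Step_r%d_s%d_%d", r, j, t)),
                            "PathwayStep")
        counts[["PathwayStep"]] <- counts[["PathwayStep"]] + 1L
        .acc_add(acc, sp, bp3("pathwayOrder"), st)
        if (!is.null(prev_step)) .acc_add(acc, prev_step, bp3("nextStep"), st)
        prev_step <- st
        for (m in seq_len(spec$reactions_per_step)) {
          rx <- .acc_instance(
            acc, .ex(sprintf("Reaction_r%d_s%d_%d_%d", r, j, t, m)),
            "BiochemicalReaction", sprintf("Reaction %d.%d.%d.%d", r, j, t, m))
          counts[["BiochemicalReaction"]] <-
            counts[["BiochemicalReaction"]] + 1L
          .acc_add(acc, sp, bp3("pathwayComponent"), rx)
          .acc_add(acc, st, bp3("stepProcess"), rx)
          if (t == 1 && m == 1) sub_entry_rxn <- c(sub_entry_rxn, rx)
        }
      }
    }

    # root chain slot kinds: deterministic quotas, seeded placement
    k <- spec$chain_length
    n_control <- floor(spec$control_step_fraction * k)
    n_sub <- min(spec$subpathways_per_root, k - n_control)
    n_direct <- k - n_control - n_sub
    kinds <- sample(c(rep("direct", n_direct), rep("sub", n_sub),
                      rep("control", n_control)))

    prev_step <- NULL
    last_rxn <- NULL
    sub_i <- 0L
    slot_rxns <- vector("list", k)   # reactions carried by each slot
    slot_kind <- character(k)
    slot_sub <- rep(NA_character_, k)
    for (i in seq_len(k)) {
      st <- .acc_instance(acc, .ex(sprintf("Step_r%d_%d", r, i)),
                          "PathwayStep")
      counts[["PathwayStep"]] <- counts[["PathwayStep"]] + 1L
      .acc_add(acc, root, bp3("pathwayOrder"), st)
      if (!is.null(prev_step)) .acc_add(acc, prev_step, bp3("nextStep"), st)
      prev_step <- st
      slot_kind[i] <- kinds[i]
      if (kinds[i] == "direct") {
        rxns <- character()
        for (m in seq_len(spec$reactions_per_step)) {
          rx <- .acc_instance(acc, .ex(sprintf("Reaction_r%d_%d_%d", r, i, m)),
                              "BiochemicalReaction",
                              sprintf("Reaction %d.%d.%d", r, i, m))
          counts[["BiochemicalReaction"]] <-
            counts[["BiochemicalReaction"]] + 1L
          .acc_add(acc, root, bp3("pathwayComponent"), rx)
          .acc_add(acc, st, bp3("stepProcess"), rx)
          if (length(participants) >= 2) {
            .acc_add(acc, rx, bp3("left"),
                     participants[(counts[["BiochemicalReaction"]] %%
                                     length(participants)) + 1L])
            .acc_add(acc, rx, bp3("right"),
                     participants[((counts[["BiochemicalReaction"]] + 1L) %%
                                     length(participants)) + 1L])
          }
          rxns <- c(rxns, rx)
          last_rxn <- rx
        }
        slot_rxns[[i]] <- rxns
      } else if (kinds[i] == "sub") {
        sub_i <- sub_i + 1L
        slot_sub[i] <- sub_iris[sub_i]
        slot_rxns[[i]] <- sub_entry_rxn[sub_i]
        .acc_add(acc, st, bp3("stepProcess"), sub_entry_rxn[sub_i])
      } else {
        ct <- .acc_instance(acc, .ex(sprintf("Catalysis_r%d_%d", r, i)),
                            "Catalysis")
        .acc_add(acc, st, bp3("stepProcess"), ct)
        if (!is.null(last_rxn)) .acc_add(acc, ct, bp3("controlled"), last_rxn)
        if (length(participants) > 0) {
          .acc_add(acc, ct, bp3("controller"), participants[1])
        }
        slot_rxns[[i]] <- character()
      }
    }

    # ground-truth derived edges: consecutive reaction-bearing slots with
    # control-only slots transparent; classification mirrors the stated
    # abstraction rules (reverse sub-to-direct pairs are not encoded)
    bearing <- which(slot_kind != "control")
    ef <- character(); et <- character(); ek <- character()
    if (length(bearing) >= 2) {
      for (q in seq_len(length(bearing) - 1L)) {
        a <- bearing[q]; b <- bearing[q + 1L]
        if (slot_kind[a] == "direct" && slot_kind[b] == "direct") {
          for (r1 in slot_rxns[[a]]) for (r2 in slot_rxns[[b]]) {
            if (r1 != r2) {
              ef <- c(ef, r1); et <- c(et, r2)
              ek <- c(ek, "NextStepBiochemicalReaction")
            }
          }
        } else if (slot_kind[a] == "direct" && slot_kind[b] == "sub") {
          for (r1 in slot_rxns[[a]]) {
            ef <- c(ef, r1); et <- c(et, slot_sub[b])
            ek <- c(ek, "NextStepPathwayFromReaction")
          }
        } else if (slot_kind[a] == "sub" && slot_kind[b] == "sub" &&
                   slot_sub[a] != slot_sub[b]) {
          ef <- c(ef, slot_sub[a]); et <- c(et, slot_sub[b])
          ek <- c(ek, "NextStepPathwayBetweenPathways")
        }
      }
    }
    edges <- dplyr::distinct(tibble::tibble(from = ef, to = et, kind = ek))
    abstract_edges[[root]] <- dplyr::arrange(edges, .data$from, .data$to,
                                             .data$kind)
  }

  tr <- dplyr::bind_rows(acc$rows)
  if (nrow(tr) == 0) tr <- .empty_triples()
  graph <- biopax_graph(tr, namespaces = c(ex = FIXTURE_NS))

  census <- tibble::tibble(source = "synthetic", class = CENSUS_CLASSES,
                           n = as.integer(counts[CENSUS_CLASSES]))
  class(census) <- c("biopax_census", class(census))
  audit_p$entities <- NULL
  audit_sm$entities <- NULL

  list(
    graph = graph,
    truth = list(
      census = census,
      audit = list(Protein = audit_p, SmallMolecule = audit_sm),
      abstract_edges = abstract_edges,
      roots = roots
    ),
    spec = spec
  )
}

#' Write a corpus ground truth as JSON
#'
#' @param truth The `truth` element of a [generate_corpus()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    census = as.list(stats::setNames(truth$census$n, truth$census$class)),
    audit = truth$audit,
    abstract_edges = lapply(truth$abstract_edges, function(e)
      as.data.frame(e)),
    roots = truth$roots
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The RNA Pol II elongation worked example
#'
#' A hand-coded miniature of the 'Formation of the RNA Pol II elongation
#' complex' pathway (Reactome R-HSA-112382): one pathway with two ordered
#' steps linked by `bp3:nextStep`, where the first step groups
#' BiochemicalReaction8726 with its activating Catalysis3256, the second
#' step carries BiochemicalReaction8727, and the second reaction consumes
#' the product of the first (the shared Complex10863). The protein
#' composition of the complexes is only partially public, so the members
#' here are synthetic stand-ins (named `*_synthetic`), sufficient for
#' structural tests.
#'
#' @return A [biopax_graph()].
#' @seealso [rna_pol2_root()]
#' @export
rna_pol2_fixture <- function() {
  ns <- REACTOME_FIXTURE_NS
  acc <- .new_acc()
  pw <- .acc_instance(acc, .ex("Pathway112382", ns), "Pathway",
                      "Formation of the RNA Pol II elongation complex")
  s1 <- .acc_instance(acc, .ex("PathwayStep10617", ns), "PathwayStep")
  s2 <- .acc_instance(acc, .ex("PathwayStep10618", ns), "PathwayStep")
  r1 <- .acc_instance(acc, .ex("BiochemicalReaction8726", ns),
                      "BiochemicalReaction",
                      "Hyperphosphorylation (Ser2) of RNA Pol II CTD by P-TEFb complex")
  r2 <- .acc_instance(acc, .ex("BiochemicalReaction8727", ns),
                      "BiochemicalReaction",
                      "Recruitment of elongation factors to form elongation complex")
  ca <- .acc_instance(acc, .ex("Catalysis3256", ns), "Catalysis")
  c1 <- .acc_instance(acc, .ex("Complex5463", ns), "Complex",
                      "RNA Pol II with phosphorylated CTD (Ser5)")
  c2 <- .acc_instance(acc, .ex("Complex10863", ns), "Complex",
                      "RNA Pol II with hyperphosphorylated CTD")
  c3 <- .acc_instance(acc, .ex("Complex10864", ns), "Complex",
                      "RNA Pol II elongation complex")
  c4 <- .acc_instance(acc, .ex("ComplexPTEFb_synthetic", ns), "Complex",
                      "P-TEFb kinase complex (synthetic stand-in)")
  p1 <- .acc_instance(acc, .ex("ProteinPOLR2A_synthetic", ns), "Protein",
                      "RNA Pol II large subunit (synthetic stand-in)")
  p2 <- .acc_instance(acc, .ex("ProteinSPT5_synthetic", ns), "Protein",
                      "Elongation factor (synthetic stand-in)")
  p3 <- .acc_instance(acc, .ex("ProteinCDK9_synthetic", ns), "Protein",
                      "P-TEFb kinase subunit (synthetic stand-in)")

  .acc_add(acc, pw, bp3("pathwayOrder"), s1)
  .acc_add(acc, pw, bp3("pathwayOrder"), s2)
  .acc_add(acc, pw, bp3("pathwayComponent"), r1)
  .acc_add(acc, pw, bp3("pathwayComponent"), r2)
  .acc_add(acc, s1, bp3("nextStep"), s2)
  .acc_add(acc, s1, bp3("stepProcess"), r1)
  .acc_add(acc, s1, bp3("stepProcess"), ca)
  .acc_add(acc, s2, bp3("stepProcess"), r2)
  .acc_add(acc, ca, bp3("controlled"), r1)
  .acc_add(acc, ca, bp3("controller"), c4)
  .acc_add(acc, r1, bp3("left"), c1)
  .acc_add(acc, r1, bp3("right"), c2)
  .acc_add(acc, r2, bp3("left"), c2)
  .acc_add(acc, r2, bp3("right"), c3)
  .acc_add(acc, c1, bp3("component"), p1)
  .acc_add(acc, c2, bp3("component"), p1)
  .acc_add(acc, c3, bp3("component"), p1)
  .acc_add(acc, c3, bp3("component"), p2)
  .acc_add(acc, c4, bp3("component"), p3)

  biopax_graph(dplyr::bind_rows(acc$rows), namespaces = c(ex = ns))
}

#' Root pathway IRI of the worked example
#' @return Character IRI of the example's Pathway instance.
#' @export
rna_pol2_root <- function() .ex("Pathway112382", REACTOME_FIXTURE_NS)
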