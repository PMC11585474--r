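# Independent brute-force oracles. These work directly on the raw triple
# tibble with base-R loops and their own constants, deliberately sharing no
# code with the implementation they check.

O_BP3 <- "http://www.biopax.org/release/biopax-level3.owl#"
O_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
obp <- function(x) paste0(O_BP3, x)

# descendant closure over a hand-written copy of the class hierarchy
o_descendants <- function(cls) {
  kids <- list(
    Entity = c("PhysicalEntity", "Interaction", "Pathway"),
    PhysicalEntity = c("Protein", "SmallMolecule", "Complex", "Dna", "Rna"),
    Interaction = c("Conversion", "Control"),
    Conversion = "BiochemicalReaction",
    Control = "Catalysis",
    EntityReference = c("ProteinReference", "SmallMoleculeReference"),
    Xref = c("UnificationXref", "RelationshipXref", "PublicationXref")
  )
  out <- cls
  repeat {
    more <- unique(unlist(kids[out]))
    more <- setdiff(more, out)
    if (length(more) == 0) return(out)
    out <- c(out, more)
  }
}

o_instances <- function(tr, classes) {
  sort(unique(tr$subject[tr$predicate == O_TYPE &
                           tr$object %in% obp(classes)]))
}

o_objects <- function(tr, subjects, pred) {
  unique(tr$object[tr$subject %in% subjects & tr$predicate == pred &
                     !tr$object_is_literal])
}

# census: direct rdf:type tally for the eight comparison classes
o_census <- function(tr) {
  cls <- c("BiochemicalReaction", "PathwayStep", "Pathway", "Interaction",
           "SmallMolecule", "Protein", "Dna", "Rna")
  vapply(cls, function(cl) length(o_instances(tr, cl)), integer(1))
}

# audit: exhaustive per-entity path enumeration
o_audit <- function(tr, entity_class, synonyms, follow_members = FALSE,
                    case_insensitive = TRUE) {
  entities <- o_instances(tr, entity_class)
  unif <- o_instances(tr, "UnificationXref")
  match_db <- function(x) {
    if (case_insensitive) tolower(x) %in% tolower(synonyms)
    else x %in% synonyms
  }
  status <- character(length(entities))
  all_ids <- character()
  for (i in seq_along(entities)) {
    refs <- o_objects(tr, entities[i], obp("entityReference"))
    if (length(refs) == 0) {
      status[i] <- "no_reference"
      next
    }
    if (follow_members) {
      repeat {
        more <- setdiff(o_objects(tr, refs, obp("memberEntityReference")),
                        refs)
        if (length(more) == 0) break
        refs <- c(refs, more)
      }
    }
    xrs <- intersect(o_objects(tr, refs, obp("xref")), unif)
    ok <- xrs[vapply(xrs, function(x) {
      dbs <- tr$object[tr$subject == x & tr$predicate == obp("db") &
                         tr$object_is_literal]
      any(match_db(dbs))
    }, TRUE)]
    if (length(ok) == 0) {
      status[i] <- "reference_no_target"
    } else {
      status[i] <- "mapped"
      all_ids <- c(all_ids, tr$object[tr$subject %in% ok &
                                        tr$predicate == obp("id") &
                                        tr$object_is_literal])
    }
  }
  list(
    n_entities = length(entities),
    n_mapped = sum(status == "mapped"),
    n_unique_ids = length(unique(all_ids)),
    n_no_reference = sum(status == "no_reference"),
    n_reference_no_target = sum(status == "reference_no_target")
  )
}

# breadth-first closure along given properties, subject to object
o_closure <- function(tr, root, props, max_depth = Inf) {
  members <- root
  frontier <- root
  d <- 0
  while (length(frontier) > 0 && d < max_depth) {
    nxt <- character()
    for (f in frontier) {
      nxt <- c(nxt, tr$object[tr$subject == f & tr$predicate %in% obp(props) &
                                !tr$object_is_literal])
    }
    frontier <- setdiff(unique(nxt), members)
    members <- c(members, frontier)
    d <- d + 1
  }
  sort(members)
}

# reactions reachable from a pathway through component/order/stepProcess
o_pathway_reactions <- function(tr, pathway) {
  pws <- o_instances(tr, "Pathway")
  seen <- pathway
  frontier <- pathway
  members <- character()
  while (length(frontier) > 0) {
    comps <- o_objects(tr, frontier, obp("pathwayComponent"))
    steps <- o_objects(tr, frontier, obp("pathwayOrder"))
    members <- union(members,
                     union(comps, o_objects(tr, steps, obp("stepProcess"))))
    frontier <- setdiff(intersect(comps, pws), seen)
    seen <- c(seen, frontier)
  }
  members
}

# step-sequence abstraction by exhaustive pair enumeration + classification
o_abstract <- function(tr, root, chain_through = TRUE) {
  follow <- c("pathwayComponent", "pathwayOrder", "nextStep", "stepProcess",
              "left", "right", "controller", "controlled", "component",
              "entityReference", "xref")
  closure <- o_closure(tr, root, follow)
  steps <- intersect(closure, o_instances(tr, "PathwayStep"))
  conv <- o_instances(tr, o_descendants("Conversion"))
  rxn_of <- lapply(steps, function(s)
    sort(intersect(o_objects(tr, s, obp("stepProcess")), conv)))
  names(rxn_of) <- steps

  comps <- o_objects(tr, root, obp("pathwayComponent"))
  direct_rxn <- intersect(comps, conv)
  direct_sub <- intersect(comps, o_instances(tr, "Pathway"))
  sub_rxns <- lapply(direct_sub, function(p) o_pathway_reactions(tr, p))
  names(sub_rxns) <- direct_sub
  subs_of <- function(r) {
    direct_sub[vapply(direct_sub, function(p) r %in% sub_rxns[[p]], TRUE)]
  }

  succ_of <- function(s) {
    out <- character(); seen <- character()
    frontier <- tr$object[tr$subject == s & tr$predicate == obp("nextStep") &
                            !tr$object_is_literal]
    frontier <- intersect(frontier, steps)
    while (length(frontier) > 0) {
      frontier <- setdiff(frontier, seen)
      seen <- c(seen, frontier)
      has <- vapply(frontier, function(x) length(rxn_of[[x]]) > 0, TRUE)
      out <- c(out, frontier[has])
      frontier <- if (chain_through) {
        intersect(unique(unlist(lapply(frontier[!has], function(x)
          tr$object[tr$subject == x & tr$predicate == obp("nextStep") &
                      !tr$object_is_literal]))), steps)
      } else character()
    }
    unique(out)
  }

  rows <- list()
  for (s1 in steps) {
    if (length(rxn_of[[s1]]) == 0) next
    for (s2 in succ_of(s1)) {
      for (r1 in rxn_of[[s1]]) for (r2 in rxn_of[[s2]]) {
        d1 <- r1 %in% direct_rxn
        d2 <- r2 %in% direct_rxn
        if (d1 && d2) {
          if (r1 != r2) rows[[length(rows) + 1L]] <-
              c(r1, r2, "NextStepBiochemicalReaction")
        } else if (d1) {
          for (sp in subs_of(r2)) rows[[length(rows) + 1L]] <-
              c(r1, sp, "NextStepPathwayFromReaction")
        } else if (!d2) {
          for (sp1 in subs_of(r1)) for (sp2 in setdiff(subs_of(r2), sp1)) {
            rows[[length(rows) + 1L]] <-
              c(sp1, sp2, "NextStepPathwayBetweenPathways")
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          kind = character()))
  }
  m <- unique(do.call(rbind, rows))
  out <- tibble::tibble(from = m[, 1], to = m[, 2], kind = m[, 3])
  out[order(out$from, out$to, out$kind), ]
}

# sorted canonical key for triple-set comparison (ignores language tags)
triple_key <- function(g) {
  tr <- if (is.data.frame(g)) g else g$triples
  sort(paste(tr$subject, tr$predicate, tr$object, tr$object_is_literal,
             ifelse(is.na(tr$datatype), "", tr$datatype), sep = "\r"))
}
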