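exn2 <- function(x) paste0("http://biopax.example/reactome#", x)

test_that("direct_components partitions pathwayComponent objects by type", {
  g <- rna_pol2_fixture()
  comps <- direct_components(g, rna_pol2_root())
  expect_setequal(comps$reactions,
                  exn2(c("BiochemicalReaction8726", "BiochemicalReaction8727")))
  expect_equal(comps$pathways, character())
  expect_error(direct_components(g, exn2("Complex5463")), "Not a Pathway")
})

test_that("a pathway with no components yields empty partitions", {
  tr <- rdf_triples(exn("PW"), O_TYPE, obp("Pathway"))
  g <- biopax_graph(tr, namespaces = c(ex = EXN))
  comps <- direct_components(g, exn("PW"))
  expect_equal(comps$reactions, character())
  expect_equal(comps$pathways, character())
})

test_that("reactions_of_step keeps conversions and excludes controls", {
  g <- rna_pol2_fixture()
  expect_equal(reactions_of_step(g, exn2("PathwayStep10617")),
               exn2("BiochemicalReaction8726"))
  expect_equal(reactions_of_step(g, exn2("PathwayStep10618")),
               exn2("BiochemicalReaction8727"))
  # a control-only step has no reactions
  tr <- dplyr::bind_rows(
    rdf_triples(exn("S"), O_TYPE, obp("PathwayStep")),
    rdf_triples(exn("C"), O_TYPE, obp("Catalysis")),
    rdf_triples(exn("S"), obp("stepProcess"), exn("C"))
  )
  g2 <- biopax_graph(tr, namespaces = c(ex = EXN))
  expect_equal(reactions_of_step(g2, exn("S")), character())
  expect_error(reactions_of_step(g, exn2("Complex5463")), "Not a PathwayStep")
})

test_that("reaction_in_pathway follows the membership closure", {
  g <- rna_pol2_fixture()
  expect_true(reaction_in_pathway(g, exn2("BiochemicalReaction8726"),
                                  rna_pol2_root()))
  # nested hierarchy against the reachability oracle
  corpus <- generate_corpus(random_spec(16))
  gg <- corpus$graph
  root <- corpus$truth$roots[1]
  rxns <- instances_of(gg, "BiochemicalReaction")
  ora <- o_pathway_reactions(gg$triples, root)
  for (r in rxns) {
    expect_equal(reaction_in_pathway(gg, r, root), r %in% ora)
  }
})

test_that("the worked example abstracts to exactly one reaction-sequence edge", {
  g <- rna_pol2_fixture()
  ab <- abstract_step_sequence(g, rna_pol2_root())
  expect_setequal(ab$reaction_nodes,
                  exn2(c("BiochemicalReaction8726", "BiochemicalReaction8727")))
  expect_equal(nrow(ab$edges), 1L)
  expect_equal(ab$edges$from, exn2("BiochemicalReaction8726"))
  expect_equal(ab$edges$to, exn2("BiochemicalReaction8727"))
  expect_equal(ab$edges$kind, "NextStepBiochemicalReaction")
  # abstraction is a genuine reduction of the low-level graph
  expect_lt(length(ab$reaction_nodes) + length(ab$pathway_nodes),
            length(unique(c(g$triples$subject, g$triples$object))))
  expect_lt(nrow(ab$edges), n_triples(g))
})

test_that("no low-level scaffolding leaks into the abstract graph", {
  for (seed in c(8, 26)) {
    corpus <- generate_corpus(random_spec(seed))
    g <- corpus$graph
    for (root in corpus$truth$roots) {
      ab <- abstract_step_sequence(g, root)
      nodes <- c(ab$reaction_nodes, ab$pathway_nodes, ab$edges$from,
                 ab$edges$to)
      banned <- c(instances_of(g, "PathwayStep"),
                  instances_of(g, "Catalysis"),
                  instances_of(g, "Stoichiometry"),
                  instances_of(g, "PhysicalEntity", include_subclasses = TRUE))
      expect_length(intersect(nodes, banned), 0L)
      comps <- direct_components(g, root)
      expect_lte(length(ab$reaction_nodes) + length(ab$pathway_nodes),
                 length(comps$reactions) + length(comps$pathways))
    }
  }
})

test_that("a single-step pathway abstracts to nodes with no edges", {
  tr <- dplyr::bind_rows(
    rdf_triples(exn("PW"), O_TYPE, obp("Pathway")),
    rdf_triples(exn("S1"), O_TYPE, obp("PathwayStep")),
    rdf_triples(exn("R1"), O_TYPE, obp("BiochemicalReaction")),
    rdf_triples(exn("PW"), obp("pathwayOrder"), exn("S1")),
    rdf_triples(exn("PW"), obp("pathwayComponent"), exn("R1")),
    rdf_triples(exn("S1"), obp("stepProcess"), exn("R1"))
  )
  ab <- abstract_step_sequence(biopax_graph(tr, namespaces = c(ex = EXN)),
                               exn("PW"))
  expect_equal(ab$reaction_nodes, exn("R1"))
  expect_equal(nrow(ab$edges), 0L)
})

test_that("a k-step chain of direct reactions yields k-1 sequence edges", {
  for (k in c(2, 5, 9)) {
    corpus <- generate_corpus(synth_spec(
      chain_length = k, reactions_per_step = 1, subpathways_per_root = 0,
      control_step_fraction = 0, n_proteins = 0, n_small_molecules = 0,
      seed = k))
    ab <- abstract_step_sequence(corpus$graph, corpus$truth$roots[1])
    expect_equal(nrow(ab$edges), k - 1L)
    expect_true(all(ab$edges$kind == "NextStepBiochemicalReaction"))
    expect_identical(ab$edges, corpus$truth$abstract_edges[[1]])
  }
})

test_that("control-only steps are transparent links by default", {
  # R1 -> control-only -> R2: chained through by default, severed otherwise
  tr <- dplyr::bind_rows(
    rdf_triples(exn("PW"), O_TYPE, obp("Pathway")),
    rdf_triples(exn(c("S1", "S2", "S3")), O_TYPE, obp("PathwayStep")),
    rdf_triples(exn(c("R1", "R2")), O_TYPE, obp("BiochemicalReaction")),
    rdf_triples(exn("C"), O_TYPE, obp("Catalysis")),
    rdf_triples(exn("PW"), obp("pathwayOrder"), exn(c("S1", "S2", "S3"))),
    rdf_triples(exn("PW"), obp("pathwayComponent"), exn(c("R1", "R2"))),
    rdf_triples(exn("S1"), obp("stepProcess"), exn("R1")),
    rdf_triples(exn("S2"), obp("stepProcess"), exn("C")),
    rdf_triples(exn("S3"), obp("stepProcess"), exn("R2")),
    rdf_triples(exn("S1"), obp("nextStep"), exn("S2")),
    rdf_triples(exn("S2"), obp("nextStep"), exn("S3")),
    rdf_triples(exn("C"), obp("controlled"), exn("R1"))
  )
  g <- biopax_graph(tr, namespaces = c(ex = EXN))
  ab <- abstract_step_sequence(g, exn("PW"))
  expect_equal(nrow(ab$edges), 1L)
  expect_equal(ab$edges$from, exn("R1"))
  expect_equal(ab$edges$to, exn("R2"))
  severed <- abstract_step_sequence(g, exn("PW"),
                                    chain_through_controls = FALSE)
  expect_equal(nrow(severed$edges), 0L)
})

test_that("abstraction equals ground truth and the exhaustive-pair oracle", {
  for (seed in c(4, 12, 33, 61)) {
    corpus <- generate_corpus(random_spec(seed))
    g <- corpus$graph
    for (root in corpus$truth$roots) {
      ab <- abstract_step_sequence(g, root)
      expect_identical(ab$edges, corpus$truth$abstract_edges[[root]])
      expect_equal(as.data.frame(ab$edges),
                   as.data.frame(o_abstract(g$triples, root)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the abstraction is independent of triple order", {
  corpus <- generate_corpus(random_spec(18))
  g <- corpus$graph
  root <- corpus$truth$roots[1]
  ref <- abstract_step_sequence(g, root)
  withr::local_seed(1)
  for (i in 1:3) {
    shuffled <- biopax_graph(
      g$triples[sample.int(nrow(g$triples)), ],
      namespaces = g$namespaces, check_vocabulary = FALSE)
    ab <- abstract_step_sequence(shuffled, root)
    expect_identical(ab$edges, ref$edges)
    expect_identical(ab$reaction_nodes, ref$reaction_nodes)
  }
})

test_that("abstract RDF output mints abs: predicates per the URI convention", {
  g <- rna_pol2_fixture()
  ab <- abstract_step_sequence(g, rna_pol2_root())
  tr <- abstract_to_triples(ab)$triples
  preds <- unique(tr$predicate[tr$predicate != O_TYPE])
  expect_equal(preds, "http://abstraction/NextStepBiochemicalReaction")

  # pathway-linking edges (both kinds) serialize as abs:NextStepPathway
  ab$edges <- tibble::tibble(
    from = exn2("BiochemicalReaction8726"), to = exn2("SubPW"),
    kind = "NextStepPathwayFromReaction")
  ab$pathway_nodes <- exn2("SubPW")
  tr2 <- abstract_to_triples(ab)$triples
  expect_true("http://abstraction/NextStepPathway" %in% tr2$predicate)
})
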