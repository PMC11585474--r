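# local alias for the worked-example namespace
exn2 <- function(x) paste0("http://biopax.example/reactome#", x)

test_that("worked-example fixture carries the expected step-chain triple", {
  g <- rna_pol2_fixture()
  tr <- g$triples
  hit <- tr$subject == exn2("PathwayStep10617") &
    tr$predicate == obp("nextStep") &
    tr$object == exn2("PathwayStep10618")
  expect_equal(sum(hit), 1L)
})

test_that("an empty RDF document parses to zero triples", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:bp3=\"http://www.biopax.org/release/biopax-level3.owl#\"/>")
  ), f)
  g <- read_biopax(f)
  expect_equal(n_triples(g), 0L)
})

test_that("serialize/parse round-trips arbitrary generated corpora", {
  for (seed in c(11, 42, 99)) {
    corpus <- generate_corpus(random_spec(seed))
    f <- withr::local_tempfile(fileext = ".owl")
    write_biopax(corpus$graph, f)
    g2 <- read_biopax(f)
    expect_identical(triple_key(corpus$graph), triple_key(g2))
  }
})

test_that("literal datatypes survive the round-trip, language tags preserved", {
  tr <- dplyr::bind_rows(
    rdf_triples(exn("P1"), O_TYPE, obp("Protein")),
    rdf_triples(exn("P1"), obp("displayName"), "EGFR <mutant> & co",
                object_is_literal = TRUE,
                datatype = "http://www.w3.org/2001/XMLSchema#string"),
    rdf_triples(exn("P1"), obp("comment"), "commentaire",
                object_is_literal = TRUE, lang = "fr")
  )
  g <- biopax_graph(tr, namespaces = c(ex = EXN))
  f <- withr::local_tempfile(fileext = ".owl")
  write_biopax(g, f)
  g2 <- read_biopax(f)
  expect_true(same_triples(g, g2))
  back <- g2$triples
  expect_equal(back$lang[back$predicate == obp("comment")], "fr")
  expect_match(back$datatype[back$predicate == obp("displayName")],
               "XMLSchema#string")
})

test_that("IO errors are reported with context", {
  expect_error(read_biopax(file.path(tempdir(), "nope.owl")), "no such file")
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines("<rdf:RDF><unclosed>", f)
  expect_error(read_biopax(f), "Malformed RDF/XML")
})

test_that("typed node elements, rdf:ID, nested nodes and blank nodes parse", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c(
    "<?xml version=\"1.0\"?>",
    paste0("<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
           " xmlns:bp3=\"http://www.biopax.org/release/biopax-level3.owl#\"",
           " xml:base=\"http://x.org/doc\">"),
    "  <bp3:Protein rdf:ID=\"p1\">",
    "    <bp3:entityReference>",
    "      <bp3:ProteinReference rdf:about=\"#pr1\"/>",
    "    </bp3:entityReference>",
    "    <bp3:displayName>EGFR</bp3:displayName>",
    "  </bp3:Protein>",
    "  <bp3:ProteinReference>",
    "    <bp3:displayName>anonymous reference</bp3:displayName>",
    "  </bp3:ProteinReference>",
    "</rdf:RDF>"
  ), f)
  g <- read_biopax(f)
  tr <- g$triples
  expect_true("http://x.org/doc#p1" %in% tr$subject)
  expect_true(any(tr$subject == "http://x.org/doc#p1" &
                    tr$predicate == obp("entityReference") &
                    tr$object == "http://x.org/doc#pr1"))
  # blank node skolemized and typed
  skolem <- tr$subject[startsWith(tr$subject, "urn:skolem:")]
  expect_length(unique(skolem), 1L)
  expect_equal(n_triples(g), 6L)
})

test_that("the Turtle convenience dialect reads the same statements", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix bp3: <http://www.biopax.org/release/biopax-level3.owl#> .",
    "@prefix ex: <http://biopax.example/test#> .",
    "ex:P1 a bp3:Protein ;",
    "  bp3:displayName \"EGFR\" ;",
    "  bp3:entityReference ex:PR1 .",
    "ex:PR1 a bp3:ProteinReference ."
  ), f)
  g <- read_biopax(f)
  expect_equal(n_triples(g), 4L)
  expect_equal(instances_of(g, "Protein"), exn("P1"))
  expect_true(any(g$triples$object == "EGFR" & g$triples$object_is_literal))
})

test_that("python rdflib parses our RDF/XML to the identical triple set", {
  corpus <- generate_corpus(random_spec(7))
  f <- withr::local_tempfile(fileext = ".owl")
  write_biopax(corpus$graph, f)
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1])",
    "for s, p, o in sorted(g):",
    "    lit = isinstance(o, rdflib.Literal)",
    "    print(str(s), str(p), str(o), int(lit), sep='\\t')"
  ), script)
  out <- system2(py, c(script, f), stdout = TRUE)
  skip_if(length(out) == 0, "rdflib unavailable")
  got <- read.delim(text = out, header = FALSE,
                    col.names = c("s", "p", "o", "lit"))
  tr <- corpus$graph$triples
  expect_equal(nrow(got), nrow(tr))
  expect_identical(
    sort(paste(got$s, got$p, got$o, got$lit)),
    sort(paste(tr$subject, tr$predicate, tr$object,
               as.integer(tr$object_is_literal)))
  )
})

test_that("instances_of matches a naive scan and nests by subclass flag", {
  for (seed in c(5, 23)) {
    corpus <- generate_corpus(random_spec(seed))
    g <- corpus$graph
    for (cl in c("Interaction", "PhysicalEntity", "Pathway", "Xref")) {
      expect_equal(instances_of(g, cl), o_instances(g$triples, cl))
      expect_equal(instances_of(g, cl, include_subclasses = TRUE),
                   o_instances(g$triples, o_descendants(cl)))
      expect_true(all(instances_of(g, cl) %in%
                        instances_of(g, cl, include_subclasses = TRUE)))
    }
  }
})

test_that("Interaction with subclasses covers the worked example's reactions", {
  g <- rna_pol2_fixture()
  got <- instances_of(g, "Interaction", include_subclasses = TRUE)
  expect_true(all(exn2(c("BiochemicalReaction8726", "BiochemicalReaction8727",
                         "Catalysis3256")) %in% got))
  expect_equal(instances_of(g, "Interaction"), character())
  expect_error(instances_of(g, "NotAClass"), "Unknown BioPAX class")
})

test_that("the shipped hierarchy has the expected shape", {
  voc <- biopax_vocabulary()
  phys <- biopax_descendants("PhysicalEntity", include_self = FALSE)
  expect_setequal(phys, c("Protein", "SmallMolecule", "Complex", "Dna", "Rna"))
  expect_true(all(c("BiochemicalReaction", "Catalysis") %in%
                    biopax_descendants("Interaction")))
  # forest: every class reaches a root by following parents, acyclically
  tab <- voc$classes
  for (cl in tab$class) {
    seen <- character()
    cur <- cl
    while (!is.na(tab$parent[tab$class == cur])) {
      expect_false(cur %in% seen)
      seen <- c(seen, cur)
      cur <- tab$parent[tab$class == cur]
    }
  }
})

test_that("graph construction dedupes and validates predicates", {
  tr <- dplyr::bind_rows(
    rdf_triples(exn("P1"), O_TYPE, obp("Protein")),
    rdf_triples(exn("P1"), O_TYPE, obp("Protein"))
  )
  g <- biopax_graph(tr, namespaces = c(ex = EXN))
  expect_equal(n_triples(g), 1L)
  bad <- rdf_triples(exn("P1"), obp("notAProperty"), exn("P2"))
  expect_error(biopax_graph(bad), "outside the shipped vocabulary")
  expect_warning(
    validate_biopax_graph(
      biopax_graph(bad, check_vocabulary = FALSE),
      on_unknown_predicate = "warn"),
    "notAProperty")
})
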