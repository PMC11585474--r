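# biopaxkit

Pathway knowledge bases (Reactome, PANTHER Pathway, PathBank, HumanCyc,
KEGG Pathway, and the PathwayCommons aggregation of them) exchange their
content as BioPAX Level 3: an RDF/OWL vocabulary in which every pathway,
reaction, molecule and cross-reference is a node in a directed labeled
graph of (subject, predicate, object) triples. That expressiveness comes
at a price — the same biology is encoded with different conventions across
databases, external identifiers hide behind multi-hop paths, and the
`PathwayStep` scaffolding that orders reactions makes even "what happens
after this reaction?" a non-trivial graph query.

biopaxkit is an R toolkit for working with these graphs as tidy tables.
It is aimed at bioinformaticians who need to compare, audit or simplify
BioPAX exports without a Java stack:

- **Parse / serialize** — BioPAX RDF/XML in and out as a deduplicated
  triple tibble (`read_biopax()`, `write_biopax()`), with a Turtle
  convenience reader and GraphML export for network tools.
- **Census** — per-class instance counts across exports with
  percentage-of-maximum normalization
  (`count_classes()`, `normalize_census()`): for each class *c* and source
  *s*, `pct[s, c] = 100 * n[s, c] / max_s' n[s', c]`.
- **Cross-reference audit** — every `Protein` (against UniProtKB) and
  `SmallMolecule` (against ChEBI) is classified into exactly one of
  *mapped*, *no reference*, or *reference without target*, by searching the
  path `entity --entityReference--> reference [--memberEntityReference-->*]
  --xref--> UnificationXref` whose `db` literal matches a configurable
  synonym policy (`audit_protein_uniprot()`, `audit_smallmolecule_chebi()`).
  The member-reference hop covers family/ortholog-style exports.
- **Extraction & views** — breadth-first closure of a pathway over a
  property whitelist (`extract_pathway_closure()`) and filtered low-level
  views with a class whitelist plus property blacklist (`filter_view()`,
  preset `simplified_view_filter()`).
- **Step-sequence abstraction** — `abstract_step_sequence()` collapses the
  `PathwayStep` layer: for steps s1 → s2 linked by `nextStep`, their
  reactions r1, r2 induce `abs:NextStepBiochemicalReaction` (r1 → r2, both
  direct components of the root), or `abs:NextStepPathway` edges
  (reaction → sub-pathway, or sub-pathway → sub-pathway), under the
  `http://abstraction/` namespace. Control-only steps are transparent
  links; no step node survives.
- **Synthetic corpora** — `generate_corpus(synth_spec(...))` emits
  seeded BioPAX corpora together with their exact expected census, audit
  partition and abstraction edge set, computed during construction.

Results are tibble-first, pipe-friendly, and carry broom-style `tidy()` /
`glance()` methods and `autoplot()` views.

## Worked example

The bundled `rna_pol2_fixture()` is a miniature of Reactome's
'Formation of the RNA Pol II elongation complex' pathway (R-HSA-112382):
two ordered steps, where the first groups BiochemicalReaction8726 with its
activating Catalysis3256, and the second reaction consumes the product of
the first.

```r
library(biopaxkit)

g <- rna_pol2_fixture()
count_classes(g, "worked example")
#> # A tibble: 8 × 3
#>   source         class                   n
#>   <chr>          <chr>               <int>
#> 1 worked example BiochemicalReaction     2
#> 2 worked example PathwayStep             2
#> 3 worked example Pathway                 1
#> 4 worked example Interaction             0
#> 5 worked example SmallMolecule           0
#> 6 worked example Protein                 3
#> 7 worked example Dna                     0
#> 8 worked example Rna                     0

abstract_step_sequence(g, rna_pol2_root())
#> <abstract_graph> root: http://biopax.example/reactome#Pathway112382
#>   2 reaction nodes, 0 sub-pathway nodes, 1 derived edges
```

The census counts direct `rdf:type` declarations (so `Interaction` is 0:
its instances here are the two `BiochemicalReaction`s and the `Catalysis`,
counted on their own axes). The abstraction removes both `PathwayStep`
nodes and the catalysis and leaves the one edge that matters:
BiochemicalReaction8726 → BiochemicalReaction8727, kind
`NextStepBiochemicalReaction`.

Auditing a synthetic corpus with known defect rates:

```r
corpus <- generate_corpus(synth_spec(seed = 3))
audit_protein_uniprot(corpus$graph)
#> <mapping_audit> Protein -> UniProtKB
#>   entities:             50
#>   mapped:               35 (28 unique ids)
#>   no reference:         10
#>   reference, no target: 5
```

The three outcomes always partition the entity set, and the unique-id
count is below the mapping count whenever several molecular states share
one entity reference.

A command-line surface (`census`, `audit`, `extract`, `abstract`,
`generate`) is installed at `inst/scripts/biopax-tools`:

```sh
Rscript inst/scripts/biopax-tools census export.owl --out census.tsv
```

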