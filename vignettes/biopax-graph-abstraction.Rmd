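---
title: "Censusing, auditing and abstracting BioPAX Level 3 graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censusing, auditing and abstracting BioPAX Level 3 graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopaxkit)
```

## The data model

BioPAX Level 3 encodes pathways as RDF: every statement is a
(subject, predicate, object) triple, and a document is a directed labeled
graph. biopaxkit represents a document as a `biopax_graph`: a deduplicated
triple tibble plus a namespace table that always carries
`bp3 = http://www.biopax.org/release/biopax-level3.owl#`. Two graphs are
considered equal when their statement sets are equal; language tags are
preserved on round-trip but excluded from statement identity, because
nothing downstream (census, audit, abstraction) depends on them, while
datatypes do participate since identifier literals must not collapse
across types.

The class hierarchy the package reasons over is shipped as a static table
(`biopax_vocabulary()`) rather than parsed from the ontology OWL at run
time, so behaviour is deterministic and needs no network. It is a forest:
entity classes root at `Entity` (with `Protein`, `SmallMolecule`,
`Complex`, `Dna`, `Rna` under `PhysicalEntity`, and `BiochemicalReaction`,
`Catalysis` under `Interaction` via `Conversion`/`Control`), while utility
classes (`PathwayStep`, `Stoichiometry`, `EntityReference`, `Xref`,
`Provenance`) root their own trees.

Parsing (`read_biopax()`) handles the striped RDF/XML used by database
exporters; blank nodes are skolemized to stable `urn:skolem:` IRIs in
document order so that round-trip equality is plain set equality. The
writer serializes subjects, predicates and objects in sorted order —
identical graphs produce byte-identical documents, which makes corpus
generation reproducible down to the file level. RDF/XML is the canonical
dialect; a small Turtle subset reader is provided as a convenience only.
Real exports may use blank nodes where this package's own output never
does; skolemization keeps such documents comparable, at the cost that
skolem IRIs are parser-assigned rather than database identifiers.

## Census across exports

`count_classes()` tallies direct `rdf:type` declarations for the eight
classes used to compare database exports. `Interaction` is counted as the
direct class only: its subclasses are separate axes of the same
comparison and a subclass closure would double-count every biochemical
reaction. Because some providers may type generic interactions under the
subclass closure, this choice is exposed as the
`interaction_subclasses` flag.

`normalize_census()` rescales each class column to percentage of its
maximum across sources. An all-zero column normalizes to 0 rather than
NaN so that downstream plots always receive finite values. The
normalization is idempotent and monotone in each count, which the test
suite asserts on randomized censuses.

## Cross-reference audit

For an entity class and a target knowledgebase, `audit_mappings()`
classifies every instance into exactly one of three outcomes:

* **mapped** — some path
  `entity --entityReference--> reference --xref--> UnificationXref`
  reaches an xref whose `db` literal matches the policy; all its `id`
  literals enter the unique-identifier pool;
* **no reference** — the entity has no `entityReference` triple at all;
* **reference without target** — a reference exists but never reaches a
  matching unification xref.

Only `UnificationXref` instances assert identity; relationship and
publication xrefs never count. The partition identity
`mapped + no_reference + reference_no_target = n_entities` is asserted on
every run, not only in tests.

Database exports disagree on the spelling of the target database:
`"UniProt"`/`"ChEBI"` in some, `"uniprot"`/`"chebi"` in others. The
`db_name_policy()` object therefore matches case-insensitively against a
configurable synonym set; enlarging the synonym set can only increase the
mapped count. Family- and ortholog-oriented exports attach the target
xref not to the reference the entity points at but to member references
below it; `follow_members = TRUE` traverses `memberEntityReference`
transitively with cycle detection, since nesting depth is not bounded by
the format. An entity with several references or several matching xrefs
counts once as mapped (it is one entity) while all its distinct
identifiers enter the unique-id pool; counting identifier pairs instead
is available from the `mapped_pairs` table of the result.

## Extraction and filtered views

`extract_pathway_closure()` computes a breadth-first closure from a
pathway root along a property whitelist, following edges from subject to
object only — the properties involved all point outward from the pathway
(to steps, processes, participants, references). The default whitelist is
the union of the structural properties plus `entityReference` and `xref`;
`max_depth` bounds the traversal, and at `max_depth = 0` the result is
the root alone. `rdf:type` and `displayName` triples of member nodes are
always retained because the census and the abstraction need typing.
Follow-property triples are kept only when both endpoints are members, so
a depth-limited closure does not dangle over its frontier.

`filter_view()` is the complementary simplification: a class whitelist
for nodes and a property blacklist for edges. The shipped
`simplified_view_filter()` preset keeps the nine structural classes of a
pathway drawing and drops the ten annotation-heavy properties
(provenance, comments, xrefs, locations, references...) that dominate raw
exports. The filter is idempotent, and composing it with extraction in
either order yields the same node set over the retained properties.

## Step-sequence abstraction

The `PathwayStep` layer encodes reaction order, but it doubles the hops
between any two reactions and pollutes topological measures (every entity
also sits two hops from everything else through shared `Provenance`
hubs). The abstraction removes that scaffolding while keeping the result
a Semantic-Web object.

Given a root pathway, the nodes of the abstract graph are the root's
*direct* components — its biochemical reactions and its sub-pathways
(`direct_components()`). For every `nextStep` pair of steps inside the
root's closure, each reaction r1 of the first step and r2 of the second
(`reactions_of_step()`, which excludes control processes grouped into the
step) induces one derived edge:

| r1 | r2 | edge |
|----|----|------|
| direct reaction | direct reaction | `NextStepBiochemicalReaction` (r1 → r2) |
| direct reaction | inside sub-pathway sp | `NextStepPathwayFromReaction` (r1 → sp) |
| inside sp1 | inside sp2 ≠ sp1 | `NextStepPathwayBetweenPathways` (sp1 → sp2) |

Membership of a reaction in a sub-pathway is the transitive closure over
`pathwayComponent` and `pathwayOrder`/`stepProcess`
(`reaction_in_pathway()`). In RDF output the first kind is minted as
`abs:NextStepBiochemicalReaction` and both pathway-linking kinds as
`abs:NextStepPathway`, with `abs: = http://abstraction/`; GraphML output
keeps the three-valued `edge_type` attribute.

Several choices here were genuinely open and are fixed as follows:

* **Steps with several reactions** produce the Cartesian product of
  derived edges — a step may group "one or more" processes and no
  tie-break is available.
* **Control-only steps are transparent** (default
  `chain_through_controls = TRUE`): a step carrying only a catalysis
  links its predecessors' reactions to its successors' reactions, so the
  reaction sequence stays connected; setting the flag to `FALSE` severs
  the chain at such steps instead.
* **Self-loops are suppressed** (r1 = r2, or sp1 = sp2): a sequence edge
  from a node to itself carries no ordering information.
* **Direction**: an edge is drawn from a direct reaction *into* a
  sub-pathway when the following reaction belongs to the sub-pathway; the
  reverse case (a sub-pathway's reaction followed by a direct reaction)
  is not encoded, only counted and reported as `n_reverse_skipped`, so
  the information is not silently lost.
* **Ambiguous membership**: a reaction that is both a direct component of
  the root and part of a sub-pathway is classified as direct.
* Step pairs outside the root's closure are ignored; abstraction is
  always relative to one root.

Duplicate derived edges collapse to one, and the edge set is returned
sorted, so the result is independent of triple iteration order.

## The synthetic-corpus generator

Analyses of full database exports cannot ship with a package, so every
module is exercised against generated corpora whose expected outputs are
known *by construction*: `generate_corpus()` returns the graph together
with the census it must produce, the exact audit partition per entity
class, and the derived edge set per root. Ground truth is accumulated
while the triples are written, never by re-running an analysis, which
keeps it an independent yardstick.

The generator covers the structures the analyses traverse: root pathways
with `nextStep` chains whose steps are direct-reaction, sub-pathway-entry
or control-only slots; sub-pathways with small internal chains; reaction
participants; and entities whose references and xrefs realize configured
defect rates. Defect allocation uses deterministic floor quotas assigned
to seeded-shuffled entities, so expected counts are exact integers with
no rounding ambiguity — 10 proteins at rates 0.2/0.1 give exactly
(7 mapped, 2 without reference, 1 without target). A configurable
fraction of mapped entities reuses the first minted reference, emulating
several molecular states of one molecule and driving the unique-id count
below the mapping count. Corpora are deterministic functions of the spec
and seed, down to byte-identical serialization.

Defaults describe the study conditions used throughout the tests: one
root with two sub-pathways and a five-step chain, 50 proteins, 30 small
molecules, defect fractions 0.2 and 0.1, both db-string dialects, and a
0.2 shared-reference fraction. What the generator does **not** emulate is
the statistical shape of real exports — degree distributions, the heavy
reuse of steps across pathways, multi-organism content, blank nodes, or
malformed cross-references beyond the two modeled defect classes. Green
property tests therefore demonstrate correctness of the graph operations
on the structures they traverse, not fidelity of any particular database;
numbers for real exports must be computed on the pinned export files
themselves.

## Numerical and scale choices

Everything here is exact set and integer arithmetic; there are no
tolerances. Degenerate inputs are defined rather than erroneous: empty
documents parse to empty graphs, empty graphs census to zeros and audit
to an all-zero partition, a pathway without components abstracts to an
empty node set, and an all-zero census column normalizes to 0. Property
tests and the acceptance script run on corpora of a few dozen pathway
elements and ~10–50 entities per class, one hundred seeds at a time —
small enough to re-derive every expectation by brute force, large enough
to cover every rule combination (the varied specs sweep sub-pathway
counts 0–2, chain lengths 3–6, control fractions 0–1/3 and one or two
reactions per step).

## Limitations

* The RDF/XML reader targets the striped subset that BioPAX exporters
  emit; exotic RDF/XML (property attributes, `parseType="Collection"`,
  reification) is out of scope.
* No OWL reasoning beyond the shipped subclass table, and no SPARQL
  front-end; queries are tibble operations.
* The vocabulary check warns (rather than errors) on bp3 properties
  outside the shipped table when reading foreign documents, since real
  exports use more of the ontology than the subset analyzed here.
* Other abstraction flavours — e.g. collapsing `entityReference`
  indirection for shortest-path work — are natural extension points, not
  implemented.
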