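Package: biopaxkit
Title: Parse, Audit and Abstract BioPAX Level 3 Pathway Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for working with BioPAX Level 3 pathway knowledge graphs
    serialized as RDF/XML. Reads and writes BioPAX documents as tidy triple
    tables, takes per-class instance censuses across database exports with
    percentage-of-maximum normalization, audits UniProtKB and ChEBI
    cross-reference mappings of proteins and small molecules (including
    member-reference traversal for family-based exports), extracts pathway
    subgraphs by property closure, builds filtered low-level views, and
    abstracts PathwayStep scaffolding into high-level reaction/pathway
    sequence graphs with typed derived edges. Ships a synthetic corpus
    generator with exact ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
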