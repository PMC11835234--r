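Package: aopnetworkr
Title: Reconstruction and Curation of Adverse Outcome Pathway Networks from
    AOP-Wiki-Shaped RDF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retrieves Adverse Outcome Pathway (AOP) entities from an
    AOP-Wiki-shaped RDF source (a local Turtle file or a SPARQL endpoint),
    reconstructs multi-AOP networks by joining pathways through shared Key
    Events, suggests merges of functionally similar Key Events by Levenshtein
    distance on their labels, applies user-confirmed merges as
    provenance-tracked node contractions, extracts degree-1/2 neighbourhoods
    with gene annotations, exports Cytoscape-compatible graphs (GraphML, SIF)
    and flat tables (CSV, XLSX), and records every operation in a replayable
    JSON-lines audit log that credits the original pathway authors.  A seeded
    synthetic fixture generator emulates the AOP-Wiki RDF shape so the whole
    pipeline runs and tests offline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
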