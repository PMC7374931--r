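Package: slcsub
Title: Substrate-Based Ontology Tools for Human Solute Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a reduced, transporter-specific chemical ontology from a
    ChEBI-style OBO file and a curated solute carrier (SLC) substrate
    annotation. The ontology is produced by extracting the subgraph reachable
    from mapped substrate terms, contracting tautomer and conjugate acid/base
    cycles, and pruning single-child non-substrate terms while preserving
    connectivity. The reduced ontology supports term-enrichment analysis of
    differentially expressed SLC sets (one-sided Fisher's exact test with
    Benjamini-Hochberg correction and most-specific-term simplification) and
    per-term binary random-forest classifiers over sequence-derived
    topological-domain features that score orphan transporters for candidate
    substrate classes. Seeded synthetic-fixture generators with analytically
    known ground truth make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC
Config/testthat/edition: 3
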