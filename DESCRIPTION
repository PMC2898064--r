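Package: finet
Title: Functional Interaction Networks from Pathways and Pairwise Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a human protein functional-interaction (FI) network by
    extracting pairwise functional interactions from curated pathway records
    (reactions and complexes) and combining them with interactions predicted by
    a naive Bayes classifier trained on nine heterogeneous pairwise-evidence
    features (physical interactions, interologs, domain-domain interactions,
    co-expression, shared Gene Ontology biological-process annotation, and
    text-mined interactions). Provides downstream cancer-genomics analysis on
    the resulting network: edge-betweenness module detection, sample-module
    co-hit permutation tests, hierarchical sample clustering, recurrence
    curves, shortest-path gene clustering with uniform and degree-stratified
    permutation significance, minimal-linker core subnetworks, and binomial
    annotation enrichment with permutation false-discovery rates. Includes
    seeded generators for synthetic pathway worlds, evidence sources and
    cancer cohorts so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
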