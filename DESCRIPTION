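Package: condnet
Title: Comparative Analysis of Condition-Associated Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and comparative analysis of condition-associated
    gene networks from typed literature-derived knowledge graphs. Extracts the
    associative network of a disease or phenotype, computes per-gene
    connectivity, betweenness centrality and cross-talk specificity
    (CTS = K/M, the fraction of a gene's global links that fall inside the
    analyzed network), tests overrepresentation of one condition's gene set in
    another by the exact hypergeometric tail in log-space, performs term
    enrichment with Bonferroni correction, partitions up to six gene sets into
    disjoint Venn regions, and classifies gene-condition links into six
    curated pattern classes. Ships a seeded generator of knowledge bases with
    planted modules, overlaps and enriched terms for end-to-end validation,
    and machine-readable transcriptions of the published hypoglycemia network
    tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
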