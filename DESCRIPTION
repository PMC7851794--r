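Package: tregmark
Title: Network-Based Discovery of Tumor-Infiltrating Treg Surface Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A marker-discovery pipeline for tumor-infiltrating regulatory
    T cells (TI-Tregs). Screens cell-surface genes that are differentially
    expressed specifically in TI-Tregs across complementary differential
    expression engines (Welch tests, a Characteristic Direction
    implementation, and a two-part zero-inflated test for single-cell
    counts), derives conserved marker and context signature sets by gene-set
    algebra and reciprocal-best-hit ortholog mapping, builds a Treg-specific
    coregulatory network from RMS-normalized expression correlations,
    ranks genes by context-associated centrality (Fisher enrichment of
    network neighbors among signature genes), and evaluates candidate
    markers as survival and therapy-response stratifiers using
    FOXP3-normalized expression scores. Ships seeded synthetic-data
    generators with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    survival,
    DESeq2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
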