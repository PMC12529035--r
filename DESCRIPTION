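Package: symscreen
Title: Convergent Gene-Loss Screening by Duplication-Loss Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phylogenomic inference of convergent gene loss across species,
    built around the presence/absence profiling of arbuscular mycorrhizal
    symbiosis genes in plants. Provides LCA-mapping duplication-loss
    reconciliation of gene trees against a rooted species tree, minimal
    duplication-loss rooting of unrooted gene trees by exhaustive search,
    anchor-based phylogenetic orthogroup extraction with an outgroup
    basalmost-ortholog rule, dual-evidence (tree plus graph cluster)
    consensus occurrence matrices with retention statistics, and a screen
    for orthogroups convergently absent in focal lineages yet present in
    background species, with exact hypergeometric enrichment. A gene-family
    birth-death simulator with trait-linked forced losses and detection
    dropout supplies ground truth so every inference stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
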