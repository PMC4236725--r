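Package: recombnet
Title: Trans-Regulators and Protein Complexes for Meiotic Recombination
    Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying candidate trans-regulatory genes
    and protein complexes associated with meiotic recombination hotspots.
    Transcription factors are prioritized by their preference for binding
    hotspots over coldspots (odds-ratio scores from motif scanning), by
    relevance derived from cross-species hotspot-binding-profile networks,
    and by a consensus ranking obtained as a minimum-cost assignment under
    Spearman's footrule. Prioritized seeds are propagated through
    protein-protein interaction networks by random walk with restart;
    dense complexes are mined from the induced top subnetwork by a
    core-attachment procedure and matched across species by maximum-weight
    bipartite matching over ortholog-based neighborhood affinity. Gene
    Ontology semantic similarity, gap scores, and hypergeometric
    enrichment support evaluation. Seeded synthetic-data generators
    emulate every input so the whole pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
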