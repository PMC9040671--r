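Package: viromeNet
Title: Virome-Bacteriome Co-Occurrence Network Analysis for Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how gut viruses (phages and eukaryotic viruses)
    interact with bacteria in disease-related metagenomic cohorts. Computes
    gene- and taxon-level relative abundance profiles from read-mapping
    summaries, estimates compositionality-corrected (SparCC-style basis)
    correlations with shuffled-matrix pseudo p-values, builds thresholded
    co-occurrence networks, derives disease-specific differential networks
    against a bootstrap null, merges networks into family-level pan- and
    core-networks, computes node importance centrality, scale-free index,
    modularity and average path length with random-graph null-model tests,
    selects key viruses by betweenness-ordered addition to the bacterial
    community, and runs link-sign permutation and Fisher functional
    enrichment tests. Includes a synthetic cohort generator with planted
    correlation structure so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
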