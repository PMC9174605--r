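Package: mitocomp
Title: Comparative Dynamics of Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of organellar genome dynamics: discovery of
    dispersed repeats by seed-and-extend self-alignment with Karlin-Altschul
    E-values, repeat age profiling by Kimura 2-parameter distance, pairwise
    shared-DNA quantification with divergence-time decay regression, absolute
    synonymous/nonsynonymous substitution rates with fold-range and clade
    summaries (including a Nei-Gojobori 1986 pairwise estimator), read-depth
    classification of cyto-nuclear gene transfer calibrated by spike-in
    reference genes, and comparative statistics over RNA-editing-site tables.
    Includes a seeded synthetic-data generator (genomes with planted repeat
    families, shared-block genome pairs, depth profiles, codon pairs) so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
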