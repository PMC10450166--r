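Package: plasmeld
Title: Two-Stage Alignment and Attention-Based Identification of Plasmid
    Contigs
Version: 0.1.0
Authors@R:
    person("Plasmeld", "Developers", email = "plasmeld@example.org",
           role = c("aut", "cre"))
Description: Identifies plasmid contigs in (meta)genomic assemblies with a
    two-stage procedure: contigs nearly identical to a reference plasmid are
    called by alignment (query coverage and identity at or above 90%), and the
    remainder are routed by host order and classified with a single-layer
    multi-head self-attention model over a protein-cluster token vocabulary.
    Includes four tokenization schemes (nucleotide byte-pair encoding, amino
    acids, amino-acid byte-pair encoding, and protein clusters built by
    all-vs-all alignment followed by Markov clustering), weighted binary
    cross-entropy training with Adam, attention-based token-importance
    reports, a synthetic order-structured genome generator for fixtures, and
    precision/recall evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
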