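Package: exomodes
Title: Binding-Mode Decomposition of ChIP-exo and ChIP-nexus Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions ChIP-exo/ChIP-nexus bound regions into binding modes,
    each defined jointly by a DNA motif (position weight matrix) and a
    strand-specific exonuclease read footprint (short Bernoulli read windows
    at learned offsets from the motif). Modes, motif locations, widths and
    window offsets are learned by collapsed Gibbs sampling with conjugate
    Dirichlet/Beta priors; the number of modes is selected by BIC. Includes
    prediction utilities (mode posteriors, confusion matrices, two-model
    log-odds classification), genomic input handling (BED summits, FASTA,
    strand-specific per-base 5'-end count tracks with optional control
    subtraction), and a synthetic-data generator with planted modes for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
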