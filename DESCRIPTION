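Package: ftcooc
Title: Transcription Factor Footprinting and Co-Occupancy Analysis for
    ATAC-Seq Cut Counts
Version: 0.9.0
Authors@R:
    person("ftcooc", "authors", email = "ftcooc@example.org",
           role = c("aut", "cre"))
Description: Genome-wide transcription-factor footprinting and co-occupancy
    analysis on ATAC-seq transposase cut-count tracks: sliding-window Poisson
    peak calling with Benjamini-Hochberg control, position-weight-matrix
    scanning with relative-score thresholds, a CENTIPEDE-style two-component
    hierarchical mixture model (negative-binomial totals, multinomial cut
    profile, logistic prior) fit by EM, promoter/enhancer annotation of
    footprints, focal-vs-partner co-occupancy enrichment against a
    background-TF null, and oPOSSUM-style promoter motif over-representation.
    Ships a synthetic cut-track generator with planted binding truth so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
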