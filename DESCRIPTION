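Package: nucruler
Title: Barrier-Aligned Nucleosome Array Quantification and the Remodeler Ruler Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies phased regular nucleosome arrays from MNase-seq-style
    dyad coverage: shifts mapped single-end reads to nucleosome dyads, builds
    barrier-aligned coverage matrices and composite plots, calls nucleosome
    peaks, and measures distance-to-barrier and linker lengths. Includes a
    continuous-time stochastic simulator of the remodeler ruler mechanism
    (position-dependent nucleosome sliding-direction bias near barriers) with
    exact birth-death and master-equation stationary-distribution oracles, and
    a synthetic MNase-seq read generator with known phasing and spacing ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    GenomeInfoDb,
    Matrix,
    Rcpp,
    stats,
    utils,
    methods,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
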