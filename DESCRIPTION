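Package: bandSELEX
Title: Band-Specific EMSA-SELEX-Seq Simulation and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing EMSA-band-specific SELEX-seq experiments on
    POU-domain transcription factors (OCT1/OCT2) with and without the BOB1
    coactivator. Provides a seeded simulator of iterative bind-select-amplify
    rounds under a position-specific affinity matrix (PSAM) binding model with
    an optional coactivator "molecular clamp", adapter-flank trimming of raw
    reads to fixed-length inserts, a degenerate-pattern (IUPAC) k-mer census
    with relative-frequency tables and positional base composition, scanning
    of the octamer/MORE/PORE motif classes including variable-length internal
    gaps, pairwise condition comparison with fold changes, and correlation of
    sequence frequencies against EMSA band intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
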