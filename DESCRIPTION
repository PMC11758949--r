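Package: bact3c
Title: Bacterial 3C/Hi-C Contact Map Analysis for Multipartite Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of binned chromosome-conformation-capture (3C/Hi-C) contact
    maps from bacteria with multipartite genomes, modelled on the Deinococcus
    radiodurans genome (chromosomes Chr1 and Chr2 plus two plasmids). Provides
    sequential component normalization (SCN) of raw contact matrices,
    directionality-index (DI) calling of chromosomal interaction domains (CIDs),
    distance-decay P(s) curves and Poisson significant-contact detection with
    Benjamini-Hochberg correction, scalogram and condition-ratio map views, a
    classical-MDS 3D embedding with radius-of-gyration and compactness metrics,
    structure-transcription integration (boundary gene tests, diagonal-expression
    correlation, sliding-window DEG enrichment, G+C profiles), and a synthetic
    contact-map generator with planted domains and truth labels for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
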