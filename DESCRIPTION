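Package: chroma3d
Title: 3D Chromatin Map Construction from Hi-C and Epigenomic Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of binned intra-chromosomal Hi-C contact
    maps together with companion epigenomic tracks: ICE matrix balancing,
    distance-decay expectation and observed/expected transformation,
    PCA-based A/B compartment calling oriented by gene density,
    insulation-score TAD detection with epigenetic clustering of domains,
    donut-background chromatin loop calling with Poisson statistics and
    Benjamini-Hochberg FDR control, accessible-chromatin-region and
    enhancer classification, loop-mediated enhancer-gene linking, SNP
    density and enrichment in regulatory elements, and two-sample
    differential accessibility. Includes a synthetic-genome simulator that
    plants compartments, TAD boundaries, loops, regulatory elements and
    expression effects with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
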