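Package: recmotifs
Title: Repeat-Motif Density and Recombination-Rate Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking short DNA repeat-motif density to
    recombination-rate variation along chromosomes. Provides multi-scale
    moving-median and local-regression smoothing of binned recombination
    maps, rho to cM/Mb normalization against genetic anchors, median-based
    segmentation into high- and low-recombining regions, letter-probability
    matrix construction from consensus motifs, a genome scanner with exact
    null score distributions, per-match p-values and Benjamini-Hochberg
    q-scores, q-discounted motif density tracks, enumerative differential
    enrichment of tandem-repeat candidates, cross-species consensus motif
    construction, and a motif-by-chromosome-by-scale association grid of
    Spearman correlations and linear regressions. Includes a synthetic-data
    generator that simulates recombination landscapes and genomes with
    planted motif occurrences for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
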