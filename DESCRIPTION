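Package: ohnoscope
Title: Post-Whole-Genome-Duplication Ohnolog Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of whole-genome duplication (WGD)
    signatures in haploid microbial eukaryote genomes, with a focus on
    facultative symbionts assayed under lifestyle-by-temperature expression
    experiments. Provides collinear gene-block detection by dynamic-programming
    chaining of homology anchors, five-way duplicate gene classification
    (singleton, dispersed, proximal, tandem, WGD/segmental), Nei-Gojobori (NG86)
    Ka/Ks estimation with Gaussian-mixture modelling of the node-averaged Ks
    distribution, negative-binomial differential-expression testing across
    lifestyle and temperature contrasts, five-group classification of ohnolog
    pair expression divergence, the tau expression-specificity index,
    differential exon usage on flattened exon counting bins, splice-junction
    conservation profiling, and pathway-level tests of preferential duplicate
    retention. A synthetic-data module generates post-WGD genomes and
    expression experiments with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust
Config/testthat/edition: 3
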