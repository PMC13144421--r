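Package: diploscan
Title: Genic Diploidization Analysis for Polyploid Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies post-polyploidization genic diploidization in plant
    genomes: homoeologous chromosome pairing from gene-rank collinearity,
    homology-based pseudogene detection and classification (duplicated,
    fragmented, processed), fractionation relative to the corresponding
    homoeolog, Kimura 2-parameter repeat divergence landscapes, intronic
    repeat burden z-scores, gene-family retention against a diploid
    outgroup, circadian promoter-motif scanning with exact p-values, and
    the physiological assay computations (flow-cytometry C-values, net
    CO2 assimilation, titratable acidity) used to characterise CAM
    physiotypes. Ships a whole-genome-duplication genome simulator that
    provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
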