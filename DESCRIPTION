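Package: slafmap
Title: SLAF-Seq Genotyping, Backcross Linkage Maps and Euclidean-Distance
    Bulked-Segregant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for reduced-representation
    (SLAF/RAD-like) marker genotyping in a first backcross (BC1) population:
    in-silico double restriction digestion of a synthetic genome, tag
    clustering and quality filtering, segregation-pattern encoding,
    genotype calling, high-density linkage-map construction (two-point LOD
    grouping, simulated-annealing marker ordering, SMOOTH-style error
    correction, k-nearest-neighbour imputation, Kosambi distances), and
    bulked-segregant mapping of a binary trait via the Euclidean-distance
    statistic between pooled allele-frequency vectors with LOESS smoothing
    and a mean + 3 SD genome-wide threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
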