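Package: carpmap
Title: Integrated Genetic and Physical Maps for Outbred F1 Mapping Families
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building genetic linkage maps from outbred full-sib
    (CP) families and integrating them with BAC-based physical maps.
    Implements segregation-distortion testing, two-point recombination
    fraction and LOD estimation with linkage-phase inference (EM over
    ambiguous genotype classes), LOD-threshold grouping, regression-style
    marker ordering with Kosambi map distances, marker-to-BAC-end-sequence
    anchoring with length/identity filters, physical-coverage and assembly
    conflict accounting, and comparative synteny analysis against a diploid
    reference genome including detection of the 2:1 linkage-group-to-
    chromosome pattern expected after a whole-genome duplication. A
    synthetic-data module simulates CP families, FPC-style contig sets and
    reference placements so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    igraph
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
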