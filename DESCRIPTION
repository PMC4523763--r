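Package: barcodegap
Title: Distance-Based DNA-Barcoding Species Delimitation with Barcoding-Gap
    Detection and Strict-Clock Dating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for distance-based species delimitation from DNA-barcode
    alignments (typically mitochondrial COI). Computes pairwise p-distances
    and Kimura 2-parameter distances under pairwise- or partial-deletion gap
    handling, with site-bootstrap standard errors; detects barcoding-gap
    candidates as zero-frequency intervals of the pairwise-distance
    distribution; delimits putative species by single-linkage threshold
    clustering with region-stratified counts; builds a neighbor-joining
    surrogate phylogeny with midpoint or outgroup rooting; and converts
    clock-like branch heights to divergence times in Ma under a strict
    molecular clock with an uncertain substitution rate. Includes a
    compositional (GC-content and GC-skew) screen for outgroup
    comparability, a seeded simulator (Yule trees, K2P sequence evolution,
    planted-partition distance matrices) for end-to-end validation, and a
    packaged fixture of a published 12-specimen centipede distance matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phytools,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
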