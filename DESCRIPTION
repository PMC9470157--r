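Package: dotlcr
Title: Dotplot-Based Detection, Typing and Composition Mapping of Protein
    Low Complexity Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects low complexity regions (LCRs) in protein sequences by
    image processing of self-comparison dotplots: binary dotplots are
    convolved with a uniform kernel, segmented at a proteome-wide intensity
    threshold calibrated to a target false discovery rate against a
    simulated length-matched null proteome, and diagonal segments are
    called as LCRs. Off-diagonal segment intersections define within-protein
    LCR types and copy numbers via graph connected components. Called LCRs
    are validated by Shannon entropy against length-matched proteome
    samples, embedded by amino-acid composition in two dimensions,
    clustered, and tested for per-residue enrichment in annotated protein
    sets. Includes a synthetic proteome generator with planted low-entropy
    blocks and brute-force oracles so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    FNN,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    uwot,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
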