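Package: tadhier
Title: Harmonizing and Benchmarking Hierarchical TAD Calls from Hi-C Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with hierarchical topologically associating
    domain (TAD) calls and the Hi-C contact matrices they are derived from.
    Harmonizes heterogeneous caller outputs into a uniform nesting-level
    scheme (level 1 = outermost domain), computes boundary levels, size
    filters, genomic coverage and level distributions, and implements a
    hierarchy-similarity metric (Hier_SSIM: mean structural similarity over
    8-Mb diagonal windows of level-valued rasters), a coding-tree overlap
    ratio, and average-linkage clustering of callers. Also provides ICE
    matrix balancing, exact contact downsampling, pseudo-bulk aggregation
    and cell-mixing simulation, boundary/TAD-body signal-enrichment
    profiles, and a synthetic generator of nested-TAD contact maps with
    distance decay and Poisson noise so every analysis is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
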