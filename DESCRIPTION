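Package: hiclipr
Title: Duplex Discovery from RNA Proximity-Ligation (hiCLIP) Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects RNA-RNA duplexes from proximity-ligation CLIP (hiCLIP)
    sequencing reads. Identifies hybrid reads carrying a linker adapter (full
    length or truncated) as well as hybrids created by direct proximity
    ligation, using a seed-and-extend partial aligner and a filter cascade to
    select a unique two-arm solution per read. Collapses PCR duplicates with a
    directional unique-molecular-identifier network, clusters overlapping
    hybrids into a duplex atlas by graph connected components, predicts
    intermolecular minimum-free-energy structures with dinucleotide-preserving
    shuffled controls, classifies duplex architecture (bulges, internal loops,
    symmetry, span classes, span mixture model), derives short-range stem-loops
    downstream of crosslink peaks from windowed base-pairing probability
    profiles, and integrates duplex atlases with RNA metabolism rates
    (k-medoid clusters, compaction scores, 3' UTR thirds). Includes a
    synthetic-data generator with planted ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    igraph,
    cluster,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
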