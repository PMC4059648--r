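Package: repeatscape
Title: Comparative Repeat Profiling of Genomes from Low-Pass Shotgun Reads
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and quantifies repetitive DNA families from low-pass
    (well below 1x coverage) shotgun reads of one or several related species.
    Reads are compared all-to-all with a k-mer seeded local aligner, similarity
    hits define a read graph, and graph clustering yields repeat clusters whose
    sizes estimate genome proportions of the underlying families. Includes
    cross-species abundance comparison, copy-number classification, cluster
    annotation against a labelled repeat reference, Lander-Waterman style
    detection probabilities, neighbor-joining phylogenetics on Jukes-Cantor
    distances, sliding-window hit-density annotation of assembled sequences,
    and a synthetic genome/read simulator with full ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    tools,
    GenomicRanges,
    igraph,
    ape,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
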