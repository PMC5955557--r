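Package: kinomevo
Title: Kinome Classification, Duplication History and Expression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for genome-wide protein kinase (kinome) family analysis:
    gating of typical kinases by Pfam-model coverage of domain hits, HMM-score
    subfamily and group assignment, neighbor-joining phylogenies under the
    p-distance model with bootstrap supports, exon-intron phase fingerprints
    restricted to the kinase domain, detection of tandem clusters and collinear
    (synteny) blocks from gene order and homology, Nei-Gojobori (1986) Ka/Ks
    estimation with Jukes-Cantor correction and Ks-epoch attribution of
    duplication events, and an RPKM-based differential-expression screen.
    A bundled synthetic-genome simulator with full ground truth makes every
    stage testable without external genome or expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
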