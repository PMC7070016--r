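Package: httscan
Title: Detection of Horizontal Transposon Transfer from TE-TE Similarity
    Hits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers horizontal transfer of transposable elements (HTT)
    between host lineages from pairwise TE-TE similarity hits. Implements
    pairwise Ka/Ks estimation by Li's (1993) degeneracy-class method on
    protein-anchored coding frames, synonymous-divergence filters against
    core-gene Ks null distributions, clustering of hits into communities
    and complete-linkage hit groups representing single transfer events,
    greedy counting of the minimal number of independent transfers,
    phylogeny-constrained species permutation tests, and selection-regime
    analysis of transferred versus within-genome TE pairs. A forward
    simulator of core-gene and TE evolution along a dated species tree,
    with planted transfer events and ground-truth labels, provides fully
    synthetic inputs for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    igraph,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
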