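Package: ldalign
Title: Non-Sequential Protein Structure Alignment from Local Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pairwise comparison of protein structures built from local
    descriptors: the backbone neighbourhood of every residue (its contact
    residues expanded into five-residue elements and merged into segments)
    is compared across two structures, and mutually consistent descriptor
    alignments are assembled into global alignments by exact branch-and-bound
    clique search with a replica-exchange Monte Carlo fallback. Alignments
    may be non-sequential (circular permutations, segment swaps) and
    non-rigid (decomposed into independently superposable rigid regions),
    and are scored by the number of aligned residues minus the square of an
    elastic "tension" term. Includes generators for protein-like synthetic
    structures (helices, hairpins, helix bundles, sheet sandwiches) with
    known ground-truth correspondences, and command-line style drivers for
    aligning, scoring and accuracy evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
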