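Package: corephylo
Title: Structure-Based Phylogenetics from Common Structural Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-order-independent multiple alignment of protein
    C-alpha traces, extraction of the common structural core shared by a
    set of homologous folds, conversion of core-based similarity scores
    to evolutionary distances, Fitch-Margoliash least-squares tree
    inference with outgroup rooting, structure-level jackknife stability
    analysis with Robinson-Foulds comparison and majority-rule consensus,
    and detection of positionally conserved residues around core columns.
    Includes a generator of synthetic fold families diverging along a
    known tree (coordinate noise, substitutions, loop indels, circular
    permutation) with full ground truth, used as the package's test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    phangorn,
    phytools,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
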