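Package: egtscreen
Title: Profile-HMM Screening and Phylogenetic Provenance Classification of
    Nuclear Pore Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a reduced endosymbiont nucleus
    (nucleomorph) retains its own nuclear pore complex. Builds and calibrates
    profile hidden Markov models from curated nucleoporin alignments, screens
    query proteomes, purges paralogous hits over iterative tree-cleaning
    cycles, classifies the phylogenetic provenance of each accepted protein
    (host versus endosymbiont/algal origin) from bootstrap-supported
    neighbor-joining trees, scores nucleomorph-targeting evidence (signal
    peptide heuristic, N-terminus completeness, FG-repeat density), and
    summarises everything as a family-by-taxon inventory matrix. A synthetic
    scenario generator with a ground-truth table makes the whole chain
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
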