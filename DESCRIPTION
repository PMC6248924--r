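Package: flagellarch
Title: Discovery and Evolutionary Analysis of Giant Flagellin Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to classify bacterial flagellins against FlgL-like decoys
    with a dual profile hidden Markov model voting scheme, to measure the
    hypervariable central insert between the conserved D0/D1 core regions,
    to discover tandem Domain-Extension (DE) repeats and the glycine-rich
    DE-eXtension (DX) insert by self alignment and iterative HMM refinement,
    and to build insert-annotated core phylogenies with a Robinson-Foulds
    congruence test between DE-copy trees and the species tree. Includes a
    synthetic flagellin evolution generator with full ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    seqinr,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
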