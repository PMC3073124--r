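Package: mpclad
Title: Maximum-Parsimony Cladistics for Discrete Morphological Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Unordered-multistate maximum parsimony for discrete
    morphological character matrices: matrix parsing and validation
    (bespoke, NEXUS and TNT dialects), Fitch/Hartigan tree-length
    optimization, heuristic search with random-addition starting trees and
    tree-bisection-reconnection branch swapping, exact branch-and-bound for
    small taxon sets, strict and majority-rule consensus, Bremer decay
    support, ensemble consistency and retention indices, ACCTRAN/DELTRAN
    synapomorphy mapping, and a seeded generator of matrices evolved on
    known trees. Ships the 78-taxon, 43-character Arminidae (Nudibranchia)
    matrix as a worked fixture with presets reproducing its published tree
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
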