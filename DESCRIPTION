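Package: dcaweights
Title: Sequence and Tree Weighting Schemes for Evolutionary Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements and compares per-sequence weighting schemes used in
    direct coupling analysis (DCA) of protein families: identity-threshold
    weights, a similarity-adjusted identity variant, Henikoff-Henikoff
    position-based weights, and the tree-based ACL (current-flow) and GSC
    (branch-partition) weights, together with a RelTime-style rescaling of
    phylogenies to relative time. Weight vectors feed a weighted
    pseudo-likelihood 21-state Potts model whose coupling scores (raw,
    average-product corrected, entropy corrected) are evaluated against
    structure-derived residue-residue contact maps via top-L positive
    predictive value. A self-contained synthetic benchmark generates trees,
    co-evolving alignments and matching toy structures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    bio3d,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
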