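Package: anchorlign
Title: Anchored Alignment and Co-Estimation for Divergent Fungal ITS Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic analysis of hypervariable fungal ITS
    (internal transcribed spacer) sequences. Implements four alignment
    strategies for ITS1-5.8S-ITS2 data: single-pass progressive alignment,
    iterative co-estimation of alignment and tree, a 5.8S "anchored"
    alignment in which the conserved 5.8S gene is replaced by a short
    constant anchor so it cannot distort alignment of the variable spacers,
    and post-alignment re-insertion of the excised 5.8S. Includes a
    neighbor-joining tree builder with bootstrap bipartition support,
    majority-rule consensus, parsimony-informative site classification,
    Robinson-Foulds and alignment-accuracy metrics, support-aware placement
    of unlabeled environmental sequences into labeled reference clades, and
    a synthetic ITS evolution simulator (multi-rate regions, indels, known
    true tree and alignment) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr,
    yaml
Config/testthat/edition: 3
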