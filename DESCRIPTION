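Package: gluscreen
Title: Discovery and Characterization of Prokaryotic Glutamate
    Receptor-Like Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A domain- and topology-based pipeline for identifying
    prokaryotic homologues of ionotropic glutamate receptor (iGluR)
    channels from protein sequence databases. Implements probe-based
    local-alignment screening with Karlin-Altschul E-values, sliding-window
    hydropathy prediction of transmembrane helices, detection of the
    re-entrant pore-loop, classification of the canonical
    S1-M1-P-M2-S2 channel topology, assignment of channels to a
    potassium-filter-bearing group and a filter-less group, construction
    of Evolutionary Domain Networks over domain compositions, region-wise
    alignment conservation summaries, tree-congruence analysis with a
    Fitch-parsimony lower bound on horizontal gene transfer, and
    reciprocal-best-hit orthology. Includes a synthetic-sequence generator
    with planted architectures and ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
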