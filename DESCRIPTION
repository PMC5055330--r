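Package: bcpf
Title: Coupled Structural Balance and Bounded-Confidence Opinion Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seedable discrete-time simulator of the BC-PF model (bounded
    confidence under preferential flip): structural-balance triad dynamics on
    complete signed networks coupled to Hegselmann-Krause bounded-confidence
    opinion formation restricted to friends.  Unbalanced triads are resolved
    by flipping the link selected by opinion distance; opinions evolve by
    averaging over friends within a confidence level.  Includes the
    local-triad-dynamics (LTD) and constrained-triad-dynamics (CTD) baselines
    of Antal, Krapivsky and Redner, a pure bounded-confidence baseline on a
    fixed all-friends network, observables for opinion segregation and clique
    structure (intra-/inter-clique diversity, opinion counts, clique-size
    difference, hyperplane separability, opinion alignment), an ensemble
    runner with parameter sweeps and threshold estimators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    quadprog,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
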