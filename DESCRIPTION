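Package: ctlesion
Title: Corticothalamic Mean-Field Simulation of White and Grey Matter Damage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates MEG-like resting-state alpha activity with a
    corticothalamic neural mass model coupled over a structural connectome,
    applies graded virtual lesions (white-matter edge damage, cortical and
    thalamic within-unit degeneration), and quantifies the functional
    consequences through alpha-band activity, phase-locking-value
    connectivity, and minimum-spanning-tree network topology (diameter and
    leaf fraction). Includes generators for synthetic connectomes and damage
    maps, a stochastic delay-differential integrator, and experiment drivers
    that aggregate outcome curves across realizations.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    signal,
    pracma,
    igraph,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
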