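Package: capnet
Title: Synthetic Cerebral Capillary Networks and Microvascular Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generation of three-dimensional synthetic cerebral capillary
    networks by constrained Voronoi tessellation with geometric pruning to
    capillary-like three-connectivity, together with deterministic lattice
    baselines (cubic and three-connected periodic lattices) and a complete
    structural and functional metric suite: AmiraMesh spatial-graph input
    and output, extravascular distance fields with box-counting space-filling
    analysis, morphometric densities, shortest capillary loop topology,
    Poiseuille network flow with Darcy permeability, transit times, a
    vessel-tissue mass exchange coefficient, and single-occlusion robustness
    campaigns. Includes ensemble reporting, convergence and scaling studies.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    graphics,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
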