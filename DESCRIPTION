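Package: popnet
Title: Sign-Constrained Pathway Convergence Analysis on Molecular Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links multiple query compounds (such as persistent organic
    pollutants) to common downstream activation targets on a signed, directed
    molecular-interaction network. Implements sign-parity-constrained simple
    path enumeration within a depth bound, discovery of convergence targets
    with per-source minimal activation depths, shortest-paths subnetwork
    assembly with iterative removal of mixed-message (concordance-conflicted)
    nodes, disease union/intersection annotation overlays, and a seeded
    planted-structure network generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
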