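Package: calmnet
Title: Overlapping Protein Complex Detection in Weighted PPI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects overlapping, variable-density protein complexes in
    edge-weighted protein-protein interaction networks with the CALM
    seed-and-extend strategy: hub-bottleneck (overlapping) nodes are
    identified from degree and betweenness and excluded from seeding,
    clusters grow greedily from seeds ranked by a support function and are
    accepted by a noise-corrected local-modularity fitness, and highly
    overlapping candidates are merged and size-filtered. Ships the standard
    complex-prediction evaluation suite (clustering-wise sensitivity,
    positive predictive value, geometric accuracy, fraction of matched
    references, and the maximum matching ratio) and a planted
    core-attachment benchmark generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: igraph, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
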