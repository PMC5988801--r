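Package: riccinet
Title: Discrete Ricci Curvature and Robustness Analysis for Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes two discretizations of Ricci curvature on undirected
    networks: Ollivier-Ricci curvature, obtained from exact Wasserstein-1
    optimal transport between random-walk neighbourhood measures, and
    Forman-Ricci curvature on weighted CW complexes, including its
    triangle-augmented variant. Provides seeded generators for four random
    graph ensembles (Erdos-Renyi, Watts-Strogatz, Barabasi-Albert and
    hyperbolic geometric graphs), classical edge- and vertex-based network
    measures (betweenness, embeddedness, dispersion, degree, clustering),
    ensemble rank-correlation experiments between measures, and robustness
    experiments under ranked edge or vertex removal scored by communication
    efficiency. Reads and writes whitespace-separated edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    boot,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
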