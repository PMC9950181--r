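Package: kintopo
Title: Persistent Homology of Genealogical and Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Topological analysis and comparison of genealogical (pedigree)
    and social networks. Builds the integer-valued clique (flag) filtration of
    a network from its geodesic distance matrix, computes persistent homology
    over Z2 in dimensions 0-2 by boundary-matrix reduction, and compares
    networks through persistence diagrams (exact bottleneck distance with a
    PCA embedding of pairwise distances) and persistence curves. Includes
    genealogy-specific analytics (distance to union, minimum cycle bases with
    familial-cycle exclusion, cycle classification), degree-1-seeded
    breadth-first subnetwork sampling, a stub-matching configuration-model
    null, and a seeded synthetic genealogy generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
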