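Package: phylogambit
Title: Testing the Phylogenetic Gambit: Surrogacy of Phylogenetic
    Diversity for Functional Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether prioritizing species by phylogenetic
    diversity (PD) captures functional diversity (FD), the so-called
    "phylogenetic gambit". Builds mixed-trait functional spaces (Gower
    distance, principal coordinates, phylogenetic signal per axis),
    implements Faith's PD with an exact greedy PD-maximizing selector,
    functional richness (FRic) as convex hull volume with a penalized
    greedy FD-maximizing selector, and measures surrogacy of PD for FD
    through accumulation curves, the area-ratio surrogacy index, and a
    reliability statistic. Includes a synthetic-data generator
    (birth-death trees, jittered tree sets, Brownian and white-noise
    traits with tunable phylogenetic signal, species pools) so the whole
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    cluster,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
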