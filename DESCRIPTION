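Package: ecoscaffold
Title: Ecological Scaffolding, Trait Endogenisation and Goldilocks Zones in
    Patchy Meta-Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic meta-population model of ecological scaffolding for
    evolutionary transitions in individuality. Particles carrying a mutable
    duplication-versus-dispersal trait live on a graph of resource-limited,
    self-renewing patches. The package computes exact collective-level life
    histories (expected propagule output and lifespan) by dynamic programming
    over the within-patch Markov chain, provides a Levins-type occupancy
    approximation of the patch network, performs adaptive-dynamics invasion
    analysis (pairwise invasibility plots, ESS location and classification,
    fold-bifurcation scans over patch size, trait-substitution trajectories,
    and a three-condition test for trait endogenisation), and runs exact
    event-driven (Gillespie) simulations of the full process with mutation on
    arbitrary patch graphs, including temporary-scaffolding and
    environmental-gradient experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
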