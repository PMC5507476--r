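Package: blastosim
Title: Rule-Based Agent Simulation of Mouse Blastocyst Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An off-lattice agent-based model of mouse preimplantation
    development. Cells are soft circles (2D) or spheres (3D) moving by
    overdamped gradient dynamics in a pairwise interaction potential with a
    polarity-dependent attraction between trophectoderm cells. Four
    developmental rules (surface polarity, FGF4-mediated fate switching,
    differential adhesion, positional apoptosis) grow a single cell into a
    blastocyst with a trophectoderm shell, cavity, and sorted
    epiblast/primitive-endoderm layers. The package scripts in silico
    perturbation experiments (rule deletions, FGF modulation and delay,
    embryo halving and aggregation), classifies endpoints into success or
    five error categories, and includes a lattice model of
    neighbour-mediated fate switching that demonstrates size-independent
    lineage ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
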