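Package: scaffopt
Title: Mechanobiological Optimization of Bone Scaffold Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a voxel finite-element model of a scaffold-filled
    critical-size long-bone defect with an agent-based model of cell-driven
    tissue regeneration, and wraps the resulting simulator in a
    kriging-surrogate global optimization loop that searches the pore-size
    design space of a cylindrical graded scaffold for the design maximizing
    regenerated bone volume in the scaffold pores at 24 weeks. Includes the
    parametric scaffold geometry and porosity computation, Prendergast-type
    mechanoregulation (octahedral shear strain plus interstitial fluid
    velocity), Latin hypercube design of experiments, DACE-style kriging,
    pattern-search, genetic and particle-swarm optimizers, and histology-style
    reporting of predicted tissue distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    lhs,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
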