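Package: featherboa
Title: Mesoscale Langevin Dynamics of a Looped Bacterial Chromosome with a
    Cytoplasmic Tracer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Langevin-dynamics simulator of the "feather-boa"
    model of the bacterial chromosome (a linear backbone decorated with closed
    side loops) together with a single cytoplasmic tracer nanoparticle, confined
    in cylindrical, spherocylindrical ("cell-like"), or slab-compressed cell
    geometries. Interactions are harmonic bonds, Weeks-Chandler-Andersen (WCA)
    pair repulsion, and 9-3 Lennard-Jones walls, integrated with a BAOAB
    Langevin scheme over a linked-cell/Verlet neighbour search. Includes the
    matching trajectory-analysis pipeline: two-dimensional projected
    mean-squared displacement, power-law (D, alpha) fits with 95% confidence
    bounds, one-dimensional step distributions with Gaussian/Laplace shape
    fits, and a fixed-packing-fraction solver for compressed-cell geometries.
    Trajectories round-trip through extended-XYZ and LAMMPS dump text, and
    systems export to LAMMPS data files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    jsonlite,
    optparse
Config/testthat/edition: 3
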