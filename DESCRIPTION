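Package: aratile
Title: Adhesion-Repulsion-Attraction Models and Lattice Symmetry Indices
    for Cellular Tile Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates nonlocal aggregation-diffusion population models of
    multicellular column patterning in which cells interact through
    short-range adhesion, medium-range repulsion and long-range attraction
    (ARA kernels), using an explicit upwind finite-volume scheme on a
    periodic square domain, for a single population and for the
    three-species R7/R8/Mi1 system of the fly medulla.  Provides the
    companion point-pattern analysis: extraction of cluster centers from
    density fields, a one-parameter centered-rectangular lattice family
    interpolating square and triangular order, bounded random lattice
    perturbations, NBH-1/2/3 neighbourhood angle statistics, and symmetry
    indices obtained by L2 fitting of empirical angle distribution
    functions against a perturbed-lattice reference library.  Includes
    parameter-sweep drivers for phase diagrams on the
    hexagonal-tetragonal axis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
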