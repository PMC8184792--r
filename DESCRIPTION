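Package: redudim
Title: Reduced-Dimension Diffusion Solvers with Unrestricted Molecular
    Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-difference solvers for diffusion and reaction-diffusion
    dynamics on periodic meshes, centred on the 1D-uFDM: a one-dimensional
    scheme that solves the two-dimensional diffusion equation inside a
    reduced-dimension (focal-plane) model by estimating off-plane
    concentrations from the in-plane profile via radial-symmetry
    interpolation at phantom points. Includes reference explicit and
    semi-implicit 1D/2D solvers, Gerschgorin stability analysis of the
    propagator matrices, a mass-conserved substrate-depletion
    reaction-diffusion integrator with operator splitting, and simulation
    plus analysis of FRAP (fluorescence recovery after photobleaching)
    experiments for diffusion-coefficient estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
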