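Package: gradmix
Title: Feed-Point Placement and Compartment-Model Simulation of Large-Scale Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing and mitigating concentration gradients in
    large-scale stirred-tank and bubble-column bioreactors. Implements the
    one-dimensional turbulent-diffusion eigen-series theory of feed-point
    placement (optimal axial, radial, and tangential feed coordinates from
    Bessel-function roots, mixing-time closed forms, and scale-up
    equivalence factors), a parameterised three-dimensional compartment-model
    builder with sparse transport operators, transient tracer and
    carbonate-buffer pH-pulse simulation (mixing time t95 and inhomogeneity
    number), fed-batch pseudo-steady-state Monod bioreaction fields with
    volumetric oxygen transfer, and a ten-class population balance of
    biomass-specific growth- and uptake-rate adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
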