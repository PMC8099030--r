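Package: scaledcm
Title: Scalable and Scale-Free Dynamics with Dynamic Causal Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising scalable and scale-free dynamical
    systems within a linear dynamic causal modelling (DCM) framework. A
    linear stochastic state-space model is fitted to multichannel
    timeseries by variational Laplace, and hypotheses about how effective
    connectivity transforms across system scales are scored by Bayesian
    model reduction. Includes a symplectic three-body orbit simulator
    (recovering the Kepler exponent -3/2 from simulated trajectories), a
    renormalization-group coarse-graining pipeline for lattice imaging
    data with correlation- and evidence-based estimators of the dynamical
    critical exponent, and seeded synthetic-data generators for both
    problem classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    rhdf5,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
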