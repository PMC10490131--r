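Package: rpinverse
Title: Inverse Estimation of Rolie-Poly Molecular Parameters from Steady
    Shear Rheometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of steady simple-shear rheometry
    for entangled linear polymer solutions with the single-mode non-Gaussian
    Rolie-Poly (ROuse LInear Entangled POLYmers) constitutive model. Provides
    a Newton/continuation steady-state solver for the conformation tensor and
    the resulting shear stress and first normal stress difference, a
    fully-connected neural-network surrogate of the parameter-to-stress map
    trained on forward-model samples, a sigmoid-bounded gradient-descent
    solver that recovers molecular parameters (polymer viscosity, reptation
    and Rouse times, finite extensibility, convective constraint release)
    from measured flow curves, and scripted studies of convergence, noise
    robustness and concentration scaling for entangled lambda-DNA solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
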