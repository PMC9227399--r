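Package: zaipp
Title: Kinetic Modelling of Zoledronic Acid Uptake and Isopentenyl
    Pyrophosphate Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental pharmacokinetic/pharmacodynamic models of in
    vitro zoledronic acid (ZA) cellular uptake and the resulting
    accumulation of the phosphoantigen isopentenyl pyrophosphate (IPP).
    Implements a three-state ODE model and a four-state model with an
    algebraic bound/unbound enzyme constraint, fixed-step fourth-order
    Runge-Kutta simulation with instantaneous medium-replacement (pulse)
    dosing events, ordinary least-squares parameter estimation by
    Nelder-Mead, a-posteriori practical identifiability analysis via the
    asymptotic covariance matrix, and a synthetic observation generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
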