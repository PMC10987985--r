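Package: craniospring
Title: Finite-Element Simulation of Spring-Assisted Cranioplasty Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for studying spring-assisted
    cranioplasty in sagittal craniosynostosis. Builds a parametric synthetic
    scaphocephalic calvarium with labelled sutures, parasagittal osteotomies
    and spring notches; solves quasi-static small-strain viscoelastic
    finite-element expansion with Prony shear relaxation and linear spring
    distractor conditions; computes craniometric outcomes (biparietal and
    occipitofrontal diameters, cranial index); runs an optimal space-filling
    design of experiments over five surgical parameters with response-surface
    local sensitivity analysis; and generates synthetic clinical cohorts for
    trend comparison against the simulated design space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    broom,
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
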