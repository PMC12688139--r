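Package: glvapprox
Title: Lotka-Volterra Approximations of Microbial Consumer-Resource Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates microbial consumer-resource communities with metabolite
    leakage and cross-feeding, derives their exact first-order generalized
    Lotka-Volterra approximation (effective growth rates and pairwise
    interaction matrix) by quasi-steady-state elimination of resources and
    linearization around equilibrium, and quantifies when the approximation
    fails. Includes Dirichlet-based community sampling with controlled niche
    overlap and leakage, stiff ODE integration of both models with analytic
    Jacobians, log-ratio accuracy metrics, local stability and reactivity
    comparison, and a consumer-resource timescale-separation diagnostic that
    predicts the approximation's validity horizon.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
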