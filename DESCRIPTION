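Package: symplast
Title: Cell-Based Simulation of Symplastic Growth in a Linear Leaf Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quasi-one-dimensional cell-based model of the symplastic growth
    of a monocot (wheat) leaf epidermis. Single cells follow a length-based
    Lockhart/Ortega biomechanics with explicit osmotic and turgor pressures
    driven by an imposed piecewise-linear biomass (isosmotic length) schedule;
    cell files are glued into a tissue through a shared transverse-fragment
    partition so that neighbouring files constrain each other's visible
    growth. Includes growth-zone zonation (division, transition, elongation
    zones), stochastic cell division with a truncated-normal division factor,
    kinematic fitting of growth rates to interval-averaged cell-length
    profiles, sensitivity analysis of the mechanical parameters, and
    post-simulation analytics (axial pressure profiles, per-cell pressure
    profile vectors with k-means clustering, growth curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
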