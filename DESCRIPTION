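Package: calchip
Title: Microfluidic ATP and Shear Stress Signal Generation and Endothelial
    Calcium Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulator of spatio-temporal agonist and wall shear
    stress stimulation in a two-inlet microfluidic channel and of the
    intracellular calcium response of endothelial cells cultured on the
    channel floor.  Solves the depth-averaged ATP convection-diffusion
    equation with time-dependent Taylor-Aris dispersion under pulsatile
    co-flow by an explicit finite-difference scheme, samples wall stimuli
    (ATP concentration and wall shear stress) at observation points, and
    integrates a stiff nonlinear ODE model of cytosolic calcium driven
    jointly by ATP (IP3/store release, P2X4 influx) and shear stress
    (mechanosensitive TRP channel gating via membrane strain energy).
    Includes frequency-sweep characterization of the channel's low-pass
    signal transmission and classification of unimodal versus oscillatory
    calcium response modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
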