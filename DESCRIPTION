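Package: phytomech
Title: Discrete Mass-Spring-Hinge Mechanics for Growing Plant Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional plane-stress mass-point, spring and hinge
    lattice model of turgid plant tissue. Spring and hinge stiffnesses are
    derived from a generalized orthotropic Hooke's law so that the effective
    material properties (Young's moduli, Poisson ratio, shear modulus) are
    controlled during deformation and plastic growth. Includes turgor-pressure
    loading through the tissue boundary polygon, damped Verlet relaxation to
    elastostatic equilibrium, multiplicative growth of spring resting lengths
    with threshold-triggered remeshing, and a virtual-rheometry suite
    (direct-stress, pure-shear, rotating-force and growth-drift experiments)
    that measures the effective moduli of the lattice.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
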