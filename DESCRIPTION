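Package: apaSim
Title: Annihilation-Photon Acollinearity Models and 2D PET Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo study of the two competing readings of "annihilation
    photon acollinearity follows a Gaussian distribution" in positron emission
    tomography: a Gaussian magnitude of the acollinearity angle (half-normal
    angular law, cusp-shaped image blur) versus a Gaussian 2D angular
    deviation (Rayleigh angular law, Gaussian image blur). Provides samplers
    and analytic densities for both interpretations, a polygonal 2D detector
    ring with idealized photoelectric detection, phantom activity models
    (point source with uniform background, sectored hot-spot phantom), a
    seeded true-coincidence event generator, Siddon ray-traced system
    matrices with ML-EM reconstruction, and resolution metrics including
    profile FWHM, the FWHM-equivalent mass metric, quadrature resolution
    prediction and Rayleigh-criterion spot resolvability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
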