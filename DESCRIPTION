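Package: axdi
Title: Axon Diameter Index Estimation from PGSE Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the axon diameter index of white matter
    from multi-shell pulsed gradient spin echo (PGSE) diffusion MRI.
    Implements the four-compartment minimal model of white matter diffusion
    (restricted cylinder, tortuous zeppelin, isotropic ball, stationary dot),
    a dictionary-based fitter with Rician-bias-corrected atoms solved by
    non-negative least squares, a conventional three-stage fitter (grid
    search, gradient descent, Rician Markov chain Monte Carlo), axon
    diameter index statistics for electron-microscopy diameter samples,
    a PGSE detectability simulation, and a synthetic voxel generator with
    gamma-distributed diameters and Watson orientation dispersion.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite, pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
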