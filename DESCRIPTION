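Package: gliostat
Title: Stationalized Reaction-Diffusion Estimation of Glioma Invasion Extent
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the invisible invasion extent of
    glioblastoma from a single imaging snapshot.  Implements forward
    reaction-diffusion(-advection) tumor-growth solvers on structured grids
    with multilinear finite elements, the closed-form wave-pinning penalty
    derived from the Fisher-KPP co-moving limit solution, stationary Newton
    solvers localized by an internal Dirichlet constraint at the imaging
    visibility threshold, synthetic diffusion-tensor field generators
    (random isotropic perturbations, banded inhomogeneities, DTI-style
    scaling), and the level-set error metrics (symmetric difference,
    characteristic level-set distance) used to validate the stationary
    approximation against full forward simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
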