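Package: gliomech
Title: Biomechanically Coupled Modeling of Glioma Growth, Vascular
    Compression and Drug Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates brain tumor progression as a coupled biomechanical
    system: stress-regulated anisotropic growth via the multiplicative
    decomposition of the deformation gradient, quasi-static neo-Hookean
    finite-element mechanics with heterogeneous elastography-derived shear
    moduli, interstitial fluid pressure and Starling filtration, oxygen and
    cancer-cell transport with DTI-anisotropic diffusion, stress-induced
    compression of the functional vasculature, and hindered transvascular
    delivery of drugs of different sizes through vessel-wall pores.
    Includes a synthetic virtual-patient generator that emulates
    magnetic resonance elastography (MRE) and diffusion tensor imaging
    (DTI) voxel data, spherically layered tetrahedral meshing, and the
    summary statistics (intratumoral mean/SD, Sorensen-Dice overlap,
    fraction-above-threshold) used to analyse such simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
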