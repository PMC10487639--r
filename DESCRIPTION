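Package: tomatch
Title: Template Matching and Particle Localization in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Device-agnostic toolkit for locating macromolecules in
    cryo-electron tomograms by three-dimensional template matching.
    Computes the masked, locally normalized cross-correlation (LCC) of a
    reference density against a tomogram over a dense set of orientations
    via FFT, keeping the per-voxel maximum score and best orientation
    index. Includes Crowther-criterion angular sampling, CTF- and
    missing-wedge-aware template construction, iterative candidate
    extraction, bimodal Gaussian score classification with
    sensitivity/FDR/RUC estimation, spatial neighbor-density and
    lamella depth analyses, and a synthetic phantom generator for
    validation. Volumes are read and written as MRC2014 maps; particle
    annotations convert between a native XML schema and RELION 3.1 STAR
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    xml2,
    minpack.lm,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: fftw3
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
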