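Package: dotdepth
Title: Depth Discrimination for Parallel-Plate Diffuse Optical Transmission Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the depth of absorbing structures from paired off-axis
    detector scans in parallel-plate, transmission-mode diffuse optical
    imaging (e.g. optical mammography). Implements a first-order Born
    perturbation forward model in the infinite-medium diffusion
    approximation, construction and inversion of the depth curve relating
    the detector-pair offset parameter alpha to relative depth z/d0,
    second-derivative ridge enhancement and skeletonization of intensity
    scans, pairing of structures across detector images by windowed
    Frobenius inner products, weighted fusion of depth estimates from
    multiple detector pairs, and a seedable photon-migration Monte Carlo
    transport model used as a physics oracle. Includes synthetic phantom
    fixtures (rods, crossing rods, vessel-like polylines) and plain-text
    scan/scene file formats with a thin command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
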