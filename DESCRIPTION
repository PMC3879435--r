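Package: anklemorph
Title: Simulated Radiographic Morphometry of the Ankle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for quantifying how ankle positioning errors
    corrupt morphometric measurements made on planar radiographs. Generates
    synthetic ankle phantoms (distal tibia/fibula and talus) with analytically
    known morphology, renders perspective digitally reconstructed radiographs
    (DRRs) by ray casting with trilinear interpolation, measures fourteen
    morphological parameters both in 3D and on the 2D projections, sweeps
    rotational pose perturbations to build sensitivity tables, quantifies
    repeatability with ICC(3,k), and corrects projected 2D measurements back
    toward their 3D values with standard-pose linear regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
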