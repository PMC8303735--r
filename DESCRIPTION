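Package: mwii
Title: Multichannel Wide-Field Interferometric Imaging of Single-Cell Dry Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for multichannel wide-field
    interferometric imaging (MWII) of weakly scattering samples. Implements
    the scalar interferometric forward model for four-wavelength coherent
    intensities, per-pixel exhaustive ("ergodic") grid-search inversion for
    refractive-index contrast and nanoscale axial offset, conversion of
    refractive-index maps to dry-mass density via the Gladstone-Dale
    relation, refractive-index-threshold nucleus segmentation, and
    single-cell growth and heterogeneity metrics. A phantom generator
    (wafers, microspheres, synthetic cells, osmotic-shock and growth
    series) provides fully ground-truthed synthetic inputs so the entire
    pipeline is testable without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
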