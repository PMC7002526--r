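Package: octac
Title: Angular Compounding and Digital Focusing for Speckle Reduction in
    Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("octac", "maintainers", email = "octac@example.org", role = c("aut", "cre"))
Description: Tools for speckle reduction in optical coherence tomography (OCT)
    by angular compounding. Provides a Gaussian-beam optics model of an
    offset-scanner OCT system, an analytic and Monte-Carlo model of speckle
    formation and its suppression by angle-induced phase averaging, a
    physics-based simulator of angle-coded complex B-scans of bead phantoms
    and scattering media (with fully developed speckle and shot noise),
    geometric image registration of angular images into physical space,
    matched-filter digital focusing of complex B-scans, image quality metrics
    (high-frequency ratio, relative standard deviation, contrast,
    contrast-to-noise ratio, full width at half maximum), and an end-to-end
    processing pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
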