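Package: hgofit
Title: Anisotropic Hyperelastic Characterization of the Annulus Fibrosus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating the Holzapfel-Gasser-Ogden (HGO)
    anisotropic hyperelastic model of the intervertebral disc annulus
    fibrosus against uniaxial stress-strain data.  Implements the
    Neo-Hookean ground-substance sub-model and its conversions to
    equivalent elastic constants, virtual uniaxial compression and
    tension specimen tests as homogeneous deformations with traction-free
    lateral faces, full-factorial grid-search parameter identification
    with mean-squared-error objective and R-squared reporting, collagen
    fiber-angle statistics (including a skewness-kurtosis omnibus
    normality check and the two-standard-deviation coverage criterion),
    a material-parameter sensitivity sweep, and a synthetic-data
    generator for end-to-end testing of the characterization pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
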