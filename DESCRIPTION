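Package: insectRNL
Title: Receptor-Noise-Limited Colour Contrast Modelling for Insect Visual
    Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models chromatic discrimination of natural reflectance spectra
    (beetle cuticle, flowers, foliage) by hypothetical insect visual systems.
    Builds photoreceptor spectral sensitivities from an A1 visual-pigment
    template, red-shifts long-wavelength receptors either by long-pass
    screening-pigment filtering or by moving the template peak, assembles
    tri- and tetrachromatic visual systems with receptor densities, and
    computes receptor-noise-limited chromatic contrasts (in just-noticeable
    differences) under daylight and photon-limited twilight illumination.
    Includes a synthetic-spectra generator emulating sigmoidal flower
    reflectance, foliage with a green peak and red edge, and diverse beetle
    coloration, so the full pipeline is reproducible without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'insectRNL-package.R'
    'pigments.R'
    'spectra-io.R'
    'synthetic-data.R'
    'visual-systems.R'
    'rnl.R'
    'pipeline.R'
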