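Package: cbctqa
Title: Phantom-Based Image Quality Analysis for Radiotherapy CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated image-quality analysis for cone beam computed
    tomography (CBCT) quality assurance with an electron density phantom
    and a CatPhan-style image quality phantom. Implements relative electron
    density (RED) versus Hounsfield unit (HU) calibration with piecewise
    linear fits and z-score outlier screening, radial uniformity, uniformity
    index, integral nonuniformity, contrast-to-noise ratio, slice thickness
    from tilted-wire ramps, circular symmetry, sensitometry CT numbers,
    modulation transfer function from a thin wire, and line-pair spatial
    resolution scoring. Includes a synthetic phantom-volume generator with
    protocol-dependent HU mapping, Gaussian blur and noise, a minimal
    single-frame CT DICOM reader/writer, and a multi-site aggregator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
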