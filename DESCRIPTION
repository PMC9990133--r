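Package: paftom
Title: Virtual Rotate-Scan Photoacoustic and Fluorescence Tomography Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual dual-modality preclinical imaging instrument: a
    physics-based forward simulator for rotate-scan photoacoustic (PA)
    acquisition on a vertical-arc transducer array and multi-angle planar
    fluorescence (FL) imaging, the matching signal-conditioning and
    reconstruction algorithms (filtered back-projection for photoacoustic
    tomography, slice-wise inverse x-ray transform for fluorescence
    molecular tomography), and a quantitative characterization suite
    (Gaussian-fit spatial resolution maps, contrast-to-noise detection
    limits, origin-fixed linearity regression, multispectral spectrum
    extraction, and resolution-chart scoring) so that the instrument's
    printed characterization procedures can be exercised end-to-end on
    synthetic phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
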