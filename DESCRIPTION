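Package: lcquant
Title: Automated Targeted Quantification of LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch engine for targeted liquid chromatography-mass spectrometry
    (LC-MS) quantification: reads raw runs in mzML, mzXML or ANDI-MS netCDF
    (optionally zip-compressed), builds extracted-ion chromatograms for a list
    of quantifier ions, detects peaks by local-minima deconvolution after
    optional Savitzky-Golay smoothing, aligns retention times across runs with
    a RANSAC-fitted non-linear warp, fits six calibration-curve families
    (linear, logarithmic, power, exponential, quadratic, cubic) to standard
    runs with optional internal-standard normalization, inverts the best
    fitting curve to absolute concentrations in micromol/L, and exports
    ID-keyed CSV tables compatible with downstream metabolomics tools.
    Includes a synthetic-run generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mzR,
    ncdf4,
    pracma,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    optparse
Config/testthat/edition: 3
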