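Package: bolushsi
Title: Hyperspectral Chemometrics of Food Boluses During Oral Processing
Version: 0.1.0
Authors@R: person("bolushsi", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: An end-to-end near-infrared hyperspectral imaging (HSI) pipeline
    for quantifying moisture content, reducing sugars and chewiness of chewed
    bread boluses: black/white reflectance calibration, ENVI cube input and
    output, spectral pretreatments (Savitzky-Golay smoothing, Gaussian
    filtering, normalization), from-scratch NIPALS partial least squares
    regression and principal component regression with cross-validation,
    pixel-wise pseudo-color concentration maps, gray-level co-occurrence
    matrix contrast as a spatial-uniformity statistic, and Spearman rank
    correlation analysis. A synthetic scene generator with a Beer-Lambert
    reflectance surrogate makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
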