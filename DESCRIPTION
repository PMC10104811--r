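Package: stylospace
Title: Outline Morphometrics and Disparity of Lacewing Larval Head Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Elliptic Fourier analysis of closed two-dimensional specimen
    outlines (head capsules with piercing stylets of neuropteran larvae),
    first-harmonic normalization of the descriptors, principal-component
    morphospace construction, and disparity estimation as the sum of
    variances of morphospace scores with bootstrap and rarefaction
    resampling and Bonferroni-corrected pairwise Welch t-tests between
    group-by-time-slice subsets. Includes readers and writers for TPS
    outline files, Freeman chain codes and coefficient tables, a synthetic
    head-plus-stylet outline generator with controlled group structure for
    testing and power analysis, and a config-driven pipeline that runs the
    full analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
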