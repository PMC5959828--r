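Package: physgrid
Title: Physically Grounded Image Analysis: Registration, Segmentation
    Evaluation and Fiducial Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for N-dimensional scalar images that occupy a physical
    region in space: images carry an origin, per-axis spacing and a direction
    cosine matrix, and all operations respect that geometry.  Provides
    centered matrix-offset transforms, bounded displacement fields and
    stack-semantics composite transforms with JSON serialization; resampling
    onto arbitrary reference grids; a multi-resolution intensity-based
    registration framework (mean squares and sampled mutual information,
    gradient descent with parameter scales derived from physical shift);
    reference-segmentation construction by majority vote and the STAPLE
    expectation-maximization algorithm together with volumetric overlap and
    surface-distance evaluation; spherical fiducial localization by Otsu
    thresholding or edge detection with least-squares sphere fitting;
    MetaImage and NRRD file I/O with environment-variable resource control
    and MD5-verified manifest-based data fetching; and deterministic
    synthetic fixture generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
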