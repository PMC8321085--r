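Package: dbtvr
Title: Volume-Rendering Optimization for Digital Breast Tomosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how z-interpolation and ray-casting sampling
    distance shape the quality of volume-rendered digital breast
    tomosynthesis (DBT) data. Provides a synthetic acrylic/aluminium disk
    phantom generator with DBT-like anisotropic z-spread, z-only resampling
    of anisotropic volumes with nearest, linear, Catmull-Rom cubic and
    windowed-sinc kernels (Lanczos, Kaiser, cosine, Hann, Hamming, Blackman,
    Nuttall windows, with window half-width and z blur factor), orthographic
    front-to-back composite ray casting at 0 and 90 degrees with
    opacity-corrected sampling distance, phantom image-quality metrics
    (Gaussian-fit FWHM, contrast-to-noise ratio, profile smoothness as the
    reciprocal standard error of a regression line), and sweep/selection
    machinery that reproduces the parameter-selection and percent-change
    arithmetic of a DBT rendering optimization study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    minpack.lm,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
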