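Package: dynshape
Title: Multilevel Principal Component Analysis of Dynamic Landmark Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical shape analysis of landmark trajectories: subjects are
    observed as time-ordered landmark configurations (a blink, a smile), each
    trajectory is resampled onto a regular time grid by per-channel cubic
    spline interpolation and flattened to a feature vector, and variation is
    decomposed either by single-level principal component analysis or by a
    two-level multilevel PCA (equivalently, between-group PCA) that separates
    between-group variation of group mean trajectories from pooled
    within-group variation. Includes component-score fitting and
    standardization, mode-of-variation trajectories, seeded Monte Carlo
    generators for univariate sine-wave trajectories, a 16-point 2D eye-blink
    dataset and a 12-landmark 3D smile-like dataset, and a reporting pipeline
    with a thin command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
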