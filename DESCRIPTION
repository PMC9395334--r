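Package: markscape
Title: Marked Point Patterns from Classified Raster Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns multi-temporal classified raster imagery into marked spatial
    point patterns and analyses them with marked point process statistics.
    Provides raster tiling into fixed-size patches, a synthetic multi-temporal
    scene generator with a known class map, temporal label-propagation data
    augmentation with leak-free train/test/validation splits, a small
    LeNet-style convolutional patch classifier trained with Adam, conversion
    of classified patch grids into marked point patterns, and estimators of
    Ripley's K, the bivariate cross-K, the pair correlation function g, the
    J-function, the Clark-Evans nearest-neighbour test, mark connection
    functions p_lm(r), and the mark correlation function k_mm(r), together
    with seeded null-model simulators (homogeneous Poisson, Matern cluster,
    simple sequential inhibition, mark randomization) and Monte Carlo
    simulation envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
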