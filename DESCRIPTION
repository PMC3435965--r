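Package: biofilmspat
Title: Spatial Ecology of Surface-Attached Bacteria at Single-Cell Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative spatial-ecology analysis of biofilm micrographs at
    single-cell resolution. Segments 8-bit grayscale or two-channel
    (red/green reporter) micrographs into calibrated per-cell object tables,
    tests cell coordinate patterns against complete spatial randomness
    (nearest-neighbor distances, cluster indices, empirical distribution
    function with Monte Carlo envelopes, Holgate, Russ, Clark & Evans and
    Hopkins & Skellam indices, box-count fractal dimension), models spatial
    autocorrelation of per-cell variates (isotropic semivariograms, weighted
    least-squares model fitting with effective ranges, Moran's I, ordinary
    kriging with isopleth maps), and quantifies cell-to-cell communication in
    dual-reporter images (source-to-sensor calling distances and per-cell
    gene-expression luminosity). Includes seed-deterministic synthetic
    generators (Poisson, Thomas cluster and hard-core point processes,
    rendered cell images, two-channel communication scenes) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
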