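Package: laihet
Title: Spatial Heterogeneity of Leaf Area Index on Arable Land
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial heterogeneity (variability and structure)
    of leaf area index (LAI) on arable land. Retrieves LAI from two-band
    (NIR, Red) reflectance rasters via NDVI, per-date endmember estimation,
    fractional vegetation cover and Beer-Lambert inversion; performs
    land-use-aware masking of mixed pixels, field segmentation and
    size/plausibility filtering; computes crop-wise and overall variability
    statistics (pooled standard deviations, relative frequency distributions,
    histogram-overlap accordance, normal-distribution comparators); and
    estimates spatial structure through empirical semivariograms with
    subsampling and abundance rebalancing, fitted by a nested
    two-exponential model ladder. A synthetic agro-landscape generator
    (rectangular field mosaics, crop-specific seasonal LAI curves,
    inter-field/intra-field variance components, kilometre-scale background
    random fields, a forward NDVI sensor model) makes the full pipeline
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
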