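Package: footprintr
Title: National-Scale Human Footprint Mapping from Scored Pressure Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds human footprint (HF) index maps from spatial layers of
    human pressure. Implements a criterion-weighted scoring template for
    pressure datasets, the standard scoring cases (categorical lookup,
    exponential distance decay, logarithmic population scaling, linear
    radiance scaling, point-buffer scoring), an accessibility model of
    indirect pressure based on least-cost travel time over a
    precedence-ordered speed surface, max/sum aggregation of scored
    pressures into the HF index, and a stratified visual-validation
    protocol with tolerance kappa, RMSE and R-squared. A seeded synthetic
    landscape generator provides end-to-end testable inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
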