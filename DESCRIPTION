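Package: palmcover
Title: Land-Cover Classification and Error-Adjusted Area Accounting for
    Plantation Concessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for mapping plantation
    landscapes from multi-temporal optical and radar imagery and turning the
    map into defensible area numbers. Multi-date optical stacks are cloud
    screened and reduced by percentile-window mean compositing; NDVI, NDVI
    texture, radar temporal statistics and terrain slope are assembled into a
    17-band feature stack on a 20 m analysis grid; a random-forest classifier
    produces a six-class land-cover map (oil palm, rubber, other trees,
    shrub, bare, water) which is smoothed with a 3x3 majority filter.
    Accuracy is assessed with an error matrix (overall, user's and producer's
    accuracy) and class areas are bias-corrected with the stratified
    error-adjusted estimator, with standard errors and 95 percent confidence
    intervals. Zonal accounting overlays the map with concession, district
    and park polygons, and a small calculator converts unplanted forest area
    into carbon-emission risk. A synthetic-landscape generator with known
    ground truth makes every stage testable without any satellite download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    mgcv,
    pracma,
    randomForest,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
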