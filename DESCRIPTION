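Package: metaprop
Title: Metaproperty Analysis and Classification of Terrestrial Laser Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes population-level metrics ("metaproperties") from
    terrestrial laser scanner (TLS) pulse data -- mean first-return distance
    and intensity, the ratio of first to second returns, the no-return (gap)
    ratio, optical plane area, and Delaunay-triangulation rugosity -- and
    classifies scans with a ten-stage binary workflow built around binomial
    and Firth penalized logistic regression, with power analysis, stratified
    train/test splitting, influence diagnostics, model reduction, accuracy
    and chance-accuracy assessment, chi-squared tests, and bootstrap ROC and
    precision-recall curves. Includes a seeded ray-casting simulator of room
    and forest scenes so the full pipeline can be exercised without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    interp,
    deldir,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
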