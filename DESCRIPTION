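Package: cwrinsitu
Title: In Situ Conservation Planning for Crop Wild Relatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for global in situ conservation planning
    of crop wild relatives (CWR). From species occurrence tables and stacks of
    edaphic, geophysical and climatic layers it cleans records, fits
    presence-background maximum-entropy distribution models with
    cross-validated adequacy checks and maximum training sensitivity plus
    specificity (MAXTRSS) binarization, projects future climate ensembles to
    map climate-stable ranges, builds ecogeographic land characterization
    (ELC) zonations as a genetic-diversity proxy, quantifies protected-area
    coverage gaps under climate change, solves the minimum-set reserve problem
    with a simulated-annealing selector, and ranks priority sites by greedy
    complementarity. A synthetic-landscape generator supplies ground-truth
    worlds so every stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
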