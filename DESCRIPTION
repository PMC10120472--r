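Package: urbandiv
Title: Experienced Income Diversity of Urban Encounters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure how evenly people from different income groups
    share time at urban places, and how that experienced diversity changes
    under mobility disruptions. Implements dwell-time exposure vectors and
    evenness/entropy diversity statistics for places, individuals and census
    block groups on stay/visit panels; stay filtering, point-of-interest
    attribution and income-quantile assignment; counterfactual stratified
    downsampling of baseline visits that decomposes a diversity change into
    activity, distance and preference factors; estimation of
    exploration-and-preferential-return behavioural parameters including
    social exploration; fixed-effects regression of area-level diversity on
    sociodemographic covariates; and correlation of diversity changes with a
    policy stringency index. A synthetic-city generator driven by a social
    exploration and preferential return (Social-EPR) model provides panels
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    geosphere,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
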