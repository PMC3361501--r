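Package: nbhood
Title: Optimal Neighborhood Selection for Point-Referenced Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chooses the optimal neighborhood size for aggregating
    individual-level binary health outcomes (for example vaccine uptake)
    referenced to geographic points of residence.  Candidate neighborhoods are
    defined by fixed geographic radius, nearly fixed population, or fixed
    population filters, and the optimum is selected by leave-one-out
    cross-validation minimizing the mean squared difference between each
    point's own outcome proportion and the proportion in its surrounding
    neighborhood.  Also provides the coefficient-of-variation measure of
    local population density used to classify a study area as homogeneous,
    moderately homogeneous, or heterogeneous, and a spatial point-pattern
    simulator (homogeneous Poisson and Thomas cluster processes) with
    household sizes and spatially structured binary outcomes for method
    evaluation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
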