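Package: bloodmealnets
Title: Bipartite Blood-Meal Networks Linking Biting Diptera and Their
    Vertebrate Hosts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds weighted bipartite interaction networks from blood-meal
    records of biting flies (Diptera) and computes network-level metrics:
    interaction evenness based on Shannon diversity and the H2' network
    specialisation index with integer-feasible entropy extrema under fixed
    marginal totals. Includes a targeted domestic-host removal null model
    with z-scores against random host removal, incidence-based rarefaction
    and Chao2 extrapolation of host, Diptera and interaction richness,
    Gaussian GLMs for habitat and latitude effects with chi-square deviance
    term tests and Tukey HSD habitat contrasts, and a Dirichlet-multinomial
    synthetic-data generator that emulates the structure of compiled
    blood-meal interaction datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    emmeans,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
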