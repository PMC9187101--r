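Package: desertMF
Title: Plant Diversity, Soil Drivers and Ecosystem Multifunctionality in Arid Desert Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for biodiversity-ecosystem-multifunctionality
    studies of arid desert plant communities sampled along a water/salt gradient.
    Computes species diversity indices (richness, Shannon-Wiener, Simpson),
    Faith's phylogenetic diversity, community phylogenetic structure (MPD, MNTD
    and their standardized effect sizes NRI/NTI under a taxa-shuffle null),
    community-weighted mean traits, a z-score averaging multifunctionality index
    over four single ecosystem functions (nutrient cycling, carbon stocks, water
    regulation, wood production), bivariate regression screens, recursive
    observed-variable path analysis with standardized coefficients and NC/CFI
    fit indices, and random-forest permutation-importance ranking of single
    functions. Includes a synthetic-data generator emulating an 80-plot desert
    field design so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    randomForest,
    stats,
    utils
Suggests:
    picante,
    vegan,
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
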