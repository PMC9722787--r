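Package: phytodiet
Title: Estuarine Water Quality, Phytoplankton Community, and Fish Diet
    Electivity Analysis
Version: 0.1.0
Authors@R:
    person("Coastal Ecology", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for seasonal water-quality assessment and phytoplankton
    community analysis in tropical estuaries, with a focus on the
    plankton-to-fish trophic link. Classifies vertical mixing from CTD
    salinity casts (stratification parameter and Venice salinity zones),
    locates the salt-intrusion isohaline, scores hilsa (Tenualosa ilisha)
    habitat suitability, computes chlorophyll-a from trichromatic
    absorbances, Sedgwick-Rafter cell densities, community composition and
    Simpson diversity, percentile-based trophic state, seasonal and spatial
    nonparametric tests, starred correlation matrices, and PCA of the
    physico-chemical panel. An odds-ratio electivity index links water and
    gut phytoplankton proportions, and literature PUFA fractions attribute
    dietary fatty-acid sources. A seeded synthetic-data generator emulates
    a monsoonal estuary so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
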