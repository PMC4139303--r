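Package: otolithchem
Title: Otolith Microchemistry Habitat Classification and Mangrove Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring juvenile habitat use of coral reef fish from
    otolith trace-element chemistry and for relating adult abundance to
    mangrove extent. Reduces laser-ablation ICP-MS count-rate time series to
    elemental concentrations and limits of detection (Tukey outlier cleaning,
    external standardization against NIST 612 glass, calcium internal
    standard, linear drift correction), screens elements by detection rate and
    standard reproducibility, applies the percent-of-total compositional
    transform, tests habitat differences by permutational ANOVA, trains a
    random-forest mangrove/reef classifier with an exhaustive element-subset
    search, reconstructs habitat-use timelines along otolith growth transects
    with Dahl-Lea length back-calculation, and summarizes distance-truncated
    underwater visual censuses against standardized mangrove area. A
    synthetic-data generator emulates every input class so the whole chain is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
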