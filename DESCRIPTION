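Package: isocolony
Title: Multi-Isotope Assignment of Birds to Breeding Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether stable-isotope ratios (d2H, d13C,
    d15N) measured in feathers can assign individuals back to their breeding
    colony. Fits per-colony trivariate-normal isotope distributions and runs
    a maximum-likelihood assignment test with error-incorporated resampling
    and leave-one-out cross-validation; clusters feathers isotopically with
    within-cluster sum-of-squares model selection and MANOVA; builds ordinary
    kriging isotope basemaps with a stable variogram model; and screens
    shed-feather microsatellite genotypes for duplicate individuals using an
    allele-mismatch rule and the probability of identity. A seeded
    synthetic-data generator produces colony isotope tables and genotype
    tables with planted duplicates so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    geosphere,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
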