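Package: soilfacets
Title: Soil Microbial Community Facets and Their Links to Microbial Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how tree diversity and soil chemistry shape
    soil microbial respiration through facets of the microbial community.
    Computes facet indices from raw measurement tables (PLFA biomass,
    amplicon ASV diversity, functional-gene scores, MicroResp substrate-induced
    respiration profiles, soil stoichiometry), fits two-standard-deviation
    standardized linear effect models with AIC-based functional-form comparison
    and stepwise selection, partitions explained variance among groups of
    predictors by adjusted R-squared inclusion-exclusion, and fits recursive
    structural-equation path models by maximum likelihood with fit indices,
    standardized estimates and direct/indirect/total effect decomposition.
    Includes a synthetic-data generator that emulates a forest
    biodiversity-ecosystem-functioning experiment so the whole pipeline can be
    exercised and validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
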