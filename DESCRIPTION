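Package: firerisk
Title: Fire Persistence, Climate-Driven Fire Suitability and Climate Risk
    for Biome-Scale Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a biome-scale fire and climate-risk analysis:
    estimation of long-range fire persistence by detrended fluctuation
    analysis (DFA-1) of fire-count series; correlative modelling of fire
    occurrence from bioclimatic predictors (bioclimatic envelope, logistic
    GLM and SVM, with pseudoabsence sampling, AUC/TSS evaluation and an
    accuracy-weighted consensus); a dry-season Regional Climate Change
    Index as a climate-hazard score; and sensitivity-resilience based
    vulnerability and climate-risk indices with class-level summaries.
    Includes a fully ground-truthed synthetic-data generator (fractional
    Gaussian noise fire series, climate stacks with prescribed per-region
    changes, climate-driven fire points) so every stage can be exercised
    end to end with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    geosphere,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
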