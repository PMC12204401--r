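Package: mrhaz
Title: Mendelian Randomization for Treatment-Specific Survival with Additive Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates germline genotypes, tumor RNA-seq expression and
    treatment-specific overall survival to identify genes whose expression
    causally affects survival. Implements cis-eQTL mapping with permutation
    gene-level p-values, LD-aware instrument selection, a Cox-based pleiotropy
    screen, one-sample and two-sample Mendelian randomization with Aalen
    additive-hazard outcome models, and downstream analyses (consensus
    molecular subtype enrichment, prognostic likelihood-ratio tests, paired
    tumor/normal differential expression). A synthetic-cohort generator
    reproduces the statistical structure the analysis assumes so the whole
    pipeline runs without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
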