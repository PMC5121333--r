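Package: mTORaa
Title: Dynamic Modelling of Amino-Acid Inputs to the mTOR-AMPK Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action ordinary-differential-equation modelling of the
    insulin and amino-acid responsive mTOR-AMPK signalling network, with
    stagewise amino-acid-input model selection by an AIC-improvement rule,
    in-silico protein knockdown scans, multi-start trust-region parameter
    estimation, ensemble-correlation and profile-likelihood identifiability
    analysis, and a triple-SILAC phosphoproteomics ratio/volcano pipeline.
    Includes generators for synthetic immunoblot time courses and
    MaxQuant-style phosphosite tables so the whole workflow is testable
    end-to-end, and SBML Level 2 Version 4 import/export of all model
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    xml2,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: SystemsBiology, NetworkInference, Proteomics, TimeCourse
RoxygenNote: 7.3.3
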