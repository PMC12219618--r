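Package: fractaldbs
Title: Fractal Dimension Biomarkers for Deep Brain Stimulation Outcome Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying regional fractal dimension (FD) of brain
    structures from labelled T1-weighted MRI volumes and its relationship to
    deep brain stimulation (DBS) outcomes in Parkinson's disease. Implements
    3D box-counting FD estimation over atlas parcellations, levodopa
    equivalent daily dose (LEDD) accounting and percent-change outcome
    classification, biomarker validation statistics (group tests with false
    discovery rate control, effect sizes, covariate-adjusted severity
    regressions), LASSO/ridge feature selection with cross-validated
    shrinkage, nested-model variance decomposition, and a spectral hypergraph
    neural network classifier over multi-feature k-uniform hypergraphs.
    Ships a synthetic-data generator (3D phantoms with controllable boundary
    complexity, cohorts with planted statistical structure) so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    RNifti,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
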