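Package: urotriage
Title: Multivariable Urinary Biomarker Risk Models for Prostate Biopsy Triage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates multivariable risk models that triage men
    with a clinical suspicion of prostate cancer before an initial TRUS
    biopsy. Integrates clinical variables (age, serum PSA, DRE prostate-size
    impression, urine volume), a urinary EN2 ELISA measurement and targeted
    NanoString-style cell-free RNA probe counts. Provides positive-control
    count normalisation, a continuous Gleason-derived training label,
    bootstrap-resampled Boruta stability feature selection, random-forest
    risk scoring from out-of-bag predictions, discrimination statistics
    (stratified-bootstrap AUC intervals, paired bootstrap AUC tests,
    proportional-odds effects, BCa mean-difference estimation) and
    prevalence-adjusted decision-curve analysis with standardised net
    benefit and biopsy net-reduction curves. A seeded synthetic-cohort
    generator emulating the marker distributions of a post-DRE urine study
    makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    boot,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, GeneExpression, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'boruta.R'
    'cohort-generator.R'
    'cohort-io.R'
    'decision-analysis.R'
    'evaluation.R'
    'pipeline.R'
    'preprocess.R'
    'risk-models.R'
    'utils.R'
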