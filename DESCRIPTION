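Package: hipecMD
Title: Microdialysis Pharmacokinetics of Hyperthermic Intraperitoneal
    Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tissue pharmacokinetics of carboplatin delivered by hyperthermic
    intraperitoneal chemotherapy (HIPEC), assessed with microdialysis.
    Implements retrodialysis-by-drug calibration (relative recovery),
    conversion of dialysate concentrations to absolute free tissue
    concentrations, midpoint-timed concentration-time profiles with
    LOQ-censoring policies, non-compartmental analysis (linear up-log down
    trapezoidal AUC, terminal elimination rate constant and half-life),
    per-compartment summaries and mixed-model comparisons, together with a
    fully seeded synthetic-study generator built on double-exponential
    (Bateman) tissue kinetics with closed-form oracles, so that every stage
    of the pipeline is verifiable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'configIO.R'
    'correction.R'
    'dosing.R'
    'nca.R'
    'statsReport.R'
    'studyDesign.R'
    'syntheticData.R'
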