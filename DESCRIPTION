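Package: adherekit
Title: Medication Adherence and Persistence Phenotyping from Pharmacy
    Purchase Registers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs individual drug purchase trajectories from
    pharmacy dispensing registers and derives two drug-taking phenotypes:
    adherence, measured as the medication possession ratio (MPR) with
    treatment-break exclusion, formulation-switch truncation and
    stockpiling caps, and persistence, a binary early-discontinuation
    phenotype with right-censoring safeguards. Includes a synthetic
    register generator with known ground truth, derivation of baseline
    health and socioeconomic risk factors (including the Charlson
    comorbidity index from ICD-10 codes), multivariable logistic and
    linear association models reported as odds ratios and percentage
    change in adherence, an analytic power calculation for single-variant
    genetic association tests, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
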