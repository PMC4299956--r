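Package: voiclass
Title: VOI-Based FDG-PET Classification of Prodromal Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Atlas-driven volume-of-interest (VOI) analysis of brain FDG-PET
    for discriminating patients with mild cognitive impairment converting to
    Alzheimer-type dementia from healthy controls. Implements regional mean
    uptake extraction from labeled volumes, cerebellar reference
    normalization, meta-VOI merging, inter-hemispheric asymmetry indices,
    gender correction estimated on controls, support-vector-machine
    classification with leave-one-out cross-validation and stepwise backward
    feature elimination, a full suite of diagnostic accuracy statistics
    (likelihood ratios with Simel intervals, diagnostic odds ratio with
    log-transform intervals, ROC/AUC with bootstrap intervals, paired AUC
    comparison), and a simplified voxel-wise t-sum abnormality score as a
    comparator. A synthetic-cohort generator provides labeled phantom atlases
    and subject data with the statistical structure the analysis assumes, so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
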