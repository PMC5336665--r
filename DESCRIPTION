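Package: ncdalgo
Title: Psychometric Classification of Neurocognitive Disorders in Cohort Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based psychometric classification of DSM-5 major and mild
    neurocognitive disorder, DSM-IV dementia, and International Working Group
    (IWG) mild cognitive impairment from neuropsychological test batteries,
    informant interviews, and self-report screeners, as used in large
    population-based ageing cohorts.  Provides sex- and education-stratified
    normative z-scoring (cross-sectional level and wave-to-wave decline), a
    triage screen, a criterion-by-criterion diagnostic engine with an explicit
    missing-data policy, evaluation statistics (Cohen's kappa with bootstrap
    confidence intervals, criteria-based logistic ROC/AUC, predictive values,
    nosology overlap), and a synthetic-cohort simulator with latent diagnostic
    status and a configurable noisy expert rater so the full pipeline can be
    exercised without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    optparse,
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
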