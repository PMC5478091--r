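Package: CoDagree
Title: Concordance Evaluation of Paired Cause-of-Death Determinations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for validating minimally invasive autopsy (MIA) cause-of-death
    determinations against the complete diagnostic autopsy (CDA) gold standard.
    Grades diagnostic evidence into certainty levels via a pathology-microbiology
    lookup matrix, classifies paired verdicts into major disease categories,
    scores ICD-10 code coincidence on the chapter/block/category hierarchy, and
    computes agreement statistics: Cohen's kappa with null and large-sample
    standard errors, overall agreement, and per-category sensitivity,
    specificity, predictive values and accuracy with exact (Clopper-Pearson)
    binomial confidence intervals. Includes a synthetic paired-case generator
    with controlled misclassification and code-depth agreement for pipeline
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
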