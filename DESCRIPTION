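Package: fuzzyichd
Title: Hierarchical Fuzzy Diagnosis of Migraine and Tension-Type Headache
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid rule-based and hierarchical fuzzy inference engine for
    the ICHD-3 diagnosis of migraine without aura, probable migraine,
    tension-type headache and probable tension-type headache. Numeric headache
    features (attack count, attack duration, pain intensity) are fuzzified
    with piecewise-linear membership functions anchored at the ICHD-3 boundary
    values; pain-characteristic criterion C is a first-level fuzzy subsystem,
    accompanying-symptom criterion D is two-valued, and a third-level Mamdani
    system with min activation and weighted-average defuzzification yields
    crisp scores for the migraine and tension-type outputs. Includes
    diagnostic-test statistics (sensitivity, specificity, predictive values,
    Youden index, total consistency rate, Cohen's kappa with asymptotic
    standard errors), a seedable synthetic patient-cohort generator, file
    readers and writers for case batches and confusion matrices, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
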