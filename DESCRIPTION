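Package: fitid3
Title: Physical Fitness Evaluation and Sports-Mode Recommendation with
    ID3 Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Induces ID3 decision trees over categorical fitness-grade
    data, both the classic multiway information-gain form (including
    Quinlan-style windowed training) and a fast strictly binary variant
    whose split criterion is a second-order Maclaurin simplification of
    node entropy.  Around the trees it provides a complete college
    physical-fitness evaluation pipeline: piecewise-linear indicator
    scoring, four-grade discretization, analytic-hierarchy-process (AHP)
    indicator weighting with consistency testing, hierarchical
    secondary-to-primary-to-overall grade decisions, rule-based
    sports-mode recommendation, information-theoretic algorithm
    comparison metrics, and a seeded synthetic student-cohort generator
    with a planted grade rule for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
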