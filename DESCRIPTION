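Package: catcad
Title: Computerized Adaptive Testing and Adaptive Diagnostic Screening for
    Ordinal Symptom Item Banks
Version: 0.1.0
Authors@R:
    person("catcad", "developers", email = "catcad@example.org",
           role = c("aut", "cre"))
Description: Tools for building and simulating two complementary adaptive
    assessment engines for mental-health symptom item banks. A computerized
    adaptive test (CAT) calibrates an ordinal item bank under the bifactor
    graded-response item response theory model, scores respondents by
    expected a posteriori estimation with a posterior-standard-deviation
    stopping rule, and reports severity on a 0-100 scale. A computerized
    adaptive diagnostic (CAD) screener trains shallow extremely randomized
    tree ensembles against a binary criterion diagnosis and administers at
    most six items per session. Includes likelihood-ratio model comparison,
    loading-based item filtering, simulated-CAT tuning searches,
    cross-validated ROC/AUC validation, a synthetic-data generator for the
    full pipeline, plain-text file formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
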