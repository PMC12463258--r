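Package: icare
Title: Individualized Clinical Assessment Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recommends the next clinical feature (test, symptom, measurement)
    to acquire for an individual patient. A locally weighted logistic
    regression is fit to a pool of complete, labelled past cases using
    inverse-distance sample weights centred on the incoming patient; the
    fitted model is attributed with closed-form linear Shapley values, and
    the highest-ranked missing feature is recommended. Includes the global
    (population-level) recommender, a repeated split-sample evaluation
    harness with locally weighted and unweighted inference arms,
    Holm-adjusted pairwise arm contrasts, synthetic scenario generators with
    region-dependent informative features, and baseline selectors
    (sequential forward selection, L1-penalised selection, and an
    imputation-based explanation-guided selector).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
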