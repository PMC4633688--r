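Package: nmfselect
Title: NMF-Based Filter Feature Selection for Ordinal Clinical Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage filter feature selection for sample-by-symptom
    matrices of nonnegative ordinal severity codes, as collected in
    clinical questionnaire studies of hepatocellular carcinoma staging.
    Stage one screens out irrelevant symptoms whose positive frequency is
    low in every clinical stratum. Stage two factorizes a class- and
    sex-balanced representative subsample by Kullback-Leibler nonnegative
    matrix factorization (multiplicative updates, consensus-based rank
    selection), measures pairwise symptom redundancy on the rows of the
    basis matrix with a combined distance/correlation similarity, groups
    redundant symptoms by thresholded connected components, and compresses
    each group into a single mixed feature. A least-squares support vector
    machine with an RBF kernel, tuned by grid search under stratified
    cross-validation, scores the selected subset. A synthetic-data
    generator with planted irrelevant and redundant symptoms makes every
    stage testable without access to patient data.
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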