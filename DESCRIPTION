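Package: notescreen
Title: Pre-Referral Abuse Screening from Clinical Note Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for screening suspected child physical abuse
    from free-text clinical notes using only the portion of the record
    written before the child-abuse-pediatrics (CAP) team became involved.
    Records are truncated at the first CAP-authored note, cleaned, and
    merged into per-patient corpora; corpora are encoded as bag-of-words
    TF-IDF vectors, mean-pooled word embeddings, or a polarized
    rules-based phrase scheme (1/0/-1); multilayer perceptrons are trained
    under a repeated stratified cross-validation protocol with
    best-epoch weight selection and compared against a ridge logistic
    baseline. Interpretation tools include gradient saliency-frequency
    maps, leave-one-out rule ablation, and a frozen-encoder audit of
    dataset shift on an external corpus. A synthetic EMR generator with a
    brute-force Bayes reference makes every stage verifiable without
    access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
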