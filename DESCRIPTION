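Package: convoscreen
Title: Dementia Screening from Free-Conversation Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening dementia from transcribed free conversation.
    Implements clinical rule-based session labeling from neuropsychological
    scores (CDR, MMSE, Logical Memory II with education-dependent cutoffs),
    document embedding of morpheme and part-of-speech bigram streams trained
    with negative sampling, a subject-aware leave-one-out evaluation with
    ensemble vote-threshold classification over five model families,
    diagnostic metrics with Yates-corrected chi-square subgroup comparisons,
    a letter-length/accuracy curve, and a synthetic cohort generator for
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    glmnet,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
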