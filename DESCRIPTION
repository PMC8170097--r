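Package: speechmarkers
Title: Multilingual Speech and Language Markers of Alzheimer's Dementia from
    Picture Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts task-specific, semantic, syntactic and paralinguistic
    features from CHAT-transcribed Cookie Theft picture descriptions (and
    optional mono WAV recordings) in English and French, screens every feature
    for cross-language generalizability with Kruskal-Wallis tests and
    point-biserial effect sizes, and evaluates "all" versus "generalizable"
    feature sets in leave-one-out cross-validated AD versus healthy-control
    classification with per-language error decomposition.  A synthetic
    bilingual cohort generator with known planted group effects makes every
    stage of the pipeline testable without access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
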