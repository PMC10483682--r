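Package: nmutext
Title: Mining Social-Media Chatter About Non-Medical Use of
    Prescription Medications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end text-mining pipeline for short, noisy
    social-media posts that mention prescription medications prone to
    non-medical use (opioids, benzodiazepines, stimulants).  Provides
    corpus readers with inclusion/exclusion filtering and user
    pseudonymization, rule-based cleaning and tokenization, pluggable
    token embedding providers, a hybrid named-entity tagger
    (character-level convolutional features, a bidirectional LSTM
    encoder and a linear-chain conditional random field trained by
    exact gradient), IOB2 chunk extraction, cluster-based topic
    modelling with class-based TF-IDF term weighting and
    topics-over-time tracking, embedding-based topic coherence
    scoring, an entity-level evaluation harness (precision/recall/F1,
    holdout and k-fold cross-validation), and seeded synthetic-corpus
    generators with planted ground truth for testing every stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
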