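Package: gazepred
Title: Computational Word Predictability and Its Evaluation Against Gaze Durations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates word predictability in running text from language
    models and word embeddings, and evaluates those estimates against
    human cloze responses and eye-movement gaze durations. Implements a
    Katz back-off N-gram model with Good-Turing discounting interpolated
    with an additively smoothed in-text cache unigram, latent semantic
    analysis (tf-idf plus truncated SVD) and cosine-similarity context
    scores for pre-trained word vectors, cloze-response aggregation with
    an answer-count filter, and a roster of Gaussian linear mixed models
    with crossed random intercepts for subject, text and word compared by
    AIC and likelihood-ratio tests, including fixed-effect-removal
    residual analysis. A synthetic-data generator with a known Markov
    language and known gaze-model coefficients makes every stage
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
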