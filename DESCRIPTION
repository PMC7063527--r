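Package: stimtweet
Title: Lexicon-Based Classification of Stimulant Nonmedical Use and Side
    Effects in Tweets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pharmacovigilance text-mining pipeline for Twitter posts
    mentioning methylphenidate. Provides curated feature lexicons (personal
    nouns, nonmedical-use terms, medical-use terms, side-effect terms),
    Porter stemming and stop-word preprocessing, opinion-lexicon sentiment
    scoring, class-weighted radial-basis-function support vector machine
    classifiers with stratified cross-validated grid search, precision /
    recall / accuracy / F1 evaluation with leave-one-feature-group-out
    ablation, Cohen kappa inter-annotator agreement, a synthetic labeled
    tweet-corpus generator for end-to-end testing, and monthly trend
    aggregation of classified corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
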