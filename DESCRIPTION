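Package: regfed
Title: Regulatory Document Triage with Hybrid Semantic and Keyword Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging large regulatory document corpora for
    AI-relevant content. Implements a dual-scoring classifier that combines
    embedding-based semantic similarity to a curated reference set with
    saturating keyword-taxonomy scores, combined by OR-ensemble threshold
    logic. Includes corpus ingestion and funnel filtering, recall-constrained
    threshold grid search, decision-boundary ensemble validation, cross-agency
    bias auditing with reference-set diversification, incremental snapshot
    monitoring, and a seeded synthetic-corpus generator for benchmarking the
    whole pipeline without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
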