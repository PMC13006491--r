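# Shared fixtures, built in code. The scored medium corpus is memoized so the
# expensive pieces (embedding + keyword scoring) run once per test session.

tiny_taxonomy <- function() {
  taxonomy(ai_terms = c("a1", "machine learning"),
           legal_regulatory_terms = c("l1", "l2"),
           biomedical_terms = c("b1"))
}

make_docs <- function(n, text = "agency guidance drug safety", agency = "FDA",
                      prefix = "d", ...) {
  corpus(data.frame(doc_id = sprintf("%s-%03d", prefix, seq_len(n)),
                    agency = rep_len(agency, n), text = rep_len(text, n),
                    stringsAsFactors = FALSE, ...),
         provenance = "test fixture")
}

random_metadata_corpus <- function(n, seed) {
  # corpus with randomized metadata for filter-oracle trials
  withr_seed <- function(s, expr) { set.seed(s); expr }
  withr_seed(seed, {
    dates <- as.Date("2017-01-01") + sample.int(3500, n, replace = TRUE)
    dates[runif(n) < 0.1] <- NA
    langs <- sample(c("en", "fr", "de", NA), n, replace = TRUE,
                    prob = c(0.6, 0.15, 0.15, 0.1))
    cats <- sample(c("guidance", "drug label", "policy", NA), n, replace = TRUE)
    corpus(data.frame(doc_id = sprintf("r-%04d", seq_len(n)),
                      agency = sample(c("FDA", "EMA", "WHO"), n, replace = TRUE),
                      date = dates, language = langs, category = cats,
                      text = "agency guidance text", stringsAsFactors = FALSE),
           provenance = "random metadata fixture")
  })
}

.fixture_env <- new.env(parent = emptyenv())

scored_fixture <- function() {
  # n = 1000 labeled corpus scored against a 34 + 1 reference set
  if (!is.null(.fixture_env$scored)) return(.fixture_env$scored)
  lc <- generate_corpus(generator_params(n_docs = 1000L, seed = 2024L))
  refs <- reference_set(generate_reference_docs(n = 34, seed = 7))
  scores <- score_corpus(lc$corpus, refs)
  ts <- generate_test_set(lc, n_relevant = 25L, n_high = 8L, seed = 11L)
  .fixture_env$scored <- list(lc = lc, refs = refs, scores = scores, ts = ts)
  .fixture_env$scored
}

or_pair_template <- function() {
  list(list(score_names = c("ai_keyword_combined_score", "avg_ref_score"),
            label = "kw|avg"))
}

# Independent brute-force evaluation of one threshold config: per-document
# loop, no vectorized reuse of package internals.
brute_evaluate <- function(scores, clauses, ts) {
  pos <- character(0)
  for (i in seq_len(nrow(scores))) {
    hit <- FALSE
    for (s in names(clauses)) if (scores[[s]][i] >= clauses[[s]]) hit <- TRUE
    if (hit) pos <- c(pos, scores$doc_id[i])
  }
  list(positive_ids = pos,
       positive_rate = length(pos) / nrow(scores),
       test_recall = mean(ts$relevant_ids %in% pos),
       high_priority_recall = if (length(ts$high_confidence_ids))
         mean(ts$high_confidence_ids %in% pos) else NA_real_)
}
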