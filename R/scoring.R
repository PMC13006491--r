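#' Build the synthetic "ideal" reference document
#'
#' Concatenates every taxonomy term — AI, then legal/regulatory, then
#' biomedical, each in list order — into one pseudo-document that acts as a
#' generalized concept anchor for similarity scoring. The construction is
#' deterministic: the same taxonomy always yields byte-identical text.
#'
#' @param tax a `regfed_taxonomy`.
#' @return a one-row `regfed_corpus` flagged synthetic (agency `"OTHER"`,
#'   category `"synthetic"`).
#' @export
build_synthetic_reference <- function(tax) {
  stopifnot(inherits(tax, "regfed_taxonomy"))
  text <- paste(c(names(tax$ai_terms), names(tax$legal_regulatory_terms),
                  names(tax$biomedical_terms)), collapse = " ")
  corpus(data.frame(doc_id = "synthetic-ideal", agency = "OTHER",
                    title = "synthetic ideal reference", category = "synthetic",
                    text = text, stringsAsFactors = FALSE),
         provenance = "synthetic ideal reference")
}

#' Assemble a reference set with precomputed embeddings
#'
#' A reference set holds the curated exemplar documents ("real" references)
#' plus the synthetic ideal document built from the taxonomy, with all
#' embeddings precomputed under one backend. Average/maximum reference
#' similarity is computed over the real references only; the ideal document
#' contributes the separate `ideal_score`.
#'
#' @param real_docs a `regfed_corpus` of exemplar documents (non-empty).
#' @param tax taxonomy used to build the synthetic ideal document.
#' @param backend embedding backend shared by all scoring.
#' @param version free-text version label.
#' @return an object of class `regfed_reference_set`.
#' @export
reference_set <- function(real_docs, tax = default_taxonomy(),
                          backend = hash_backend(), version = "v1") {
  stopifnot(inherits(real_docs, "regfed_corpus"), nrow(real_docs) > 0)
  ideal <- build_synthetic_reference(tax)
  if (ideal$doc_id %in% real_docs$doc_id)
    stop("the synthetic ideal document must not appear among real references",
         call. = FALSE)
  structure(list(
    real_docs = real_docs,
    real_emb = embed_texts(real_docs$text, backend),
    ideal_doc = ideal,
    ideal_emb = embed(ideal$text[1L], backend),
    taxonomy = tax,
    backend = backend,
    version = version
  ), class = "regfed_reference_set")
}

#' @export
print.regfed_reference_set <- function(x, ...) {
  cat(sprintf("<regfed_reference_set> %d real + 1 synthetic (backend %s, %s)\n",
              nrow(x$real_docs), x$backend$name, x$version))
  invisible(x)
}

#' Reference-similarity scores for one document embedding
#'
#' @param doc_vec embedding of the document (same backend as `refs`).
#' @param refs a [reference_set()].
#' @return named list: `avg_ref_score` (mean cosine similarity over real
#'   references), `max_ref_score` (maximum), `ideal_score` (similarity to the
#'   synthetic ideal document).
#' @export
reference_scores <- function(doc_vec, refs) {
  stopifnot(inherits(refs, "regfed_reference_set"))
  if (length(doc_vec) != ncol(refs$real_emb))
    stop("backend mismatch: document embedding has dim ", length(doc_vec),
         ", references have ", ncol(refs$real_emb), call. = FALSE)
  sims <- as.numeric(refs$real_emb %*% doc_vec)
  list(avg_ref_score = mean(sims), max_ref_score = max(sims),
       ideal_score = sum(refs$ideal_emb * doc_vec))
}

# Count non-overlapping contiguous occurrences of a token phrase in a token
# vector, stopping early at `cap` (scores saturate there anyway).
count_phrase <- function(tokens, phrase, cap = Inf) {
  k <- length(phrase)
  n <- length(tokens)
  if (k == 0L || n < k) return(0L)
  if (k == 1L) return(min(sum(tokens == phrase), cap))
  starts <- which(tokens == phrase[1L])
  starts <- starts[starts <= n - k + 1L]
  cnt <- 0L
  last_end <- 0L
  for (s in starts) {
    if (s <= last_end) next
    if (all(tokens[s:(s + k - 1L)] == phrase)) {
      cnt <- cnt + 1L
      last_end <- s + k - 1L
      if (cnt >= cap) break
    }
  }
  cnt
}

#' Saturating keyword score for one terminology domain
#'
#' For weighted terms t the score is
#' `sum_t w_t * min(c_t, C) / C  /  sum_t w_t`,
#' where `c_t` counts non-overlapping case-insensitive matches of the term
#' (multi-token terms as contiguous token phrases) in the normalized text and
#' `C` is the saturation cap. The score is bounded in `[0, 1]`, monotone in
#' every count, and saturates once each term has appeared `C` times.
#'
#' @param text document text (raw; normalized internally). Alternatively a
#'   pre-tokenized character vector via `tokens`.
#' @param domain_terms named numeric vector of positive term weights (names
#'   are terms), or a character vector of terms (unit weights).
#' @param cap saturation cap `C` (default 3).
#' @param tokens optional pre-tokenized text (overrides `text`).
#' @return score in `[0, 1]`.
#' @export
keyword_domain_score <- function(text, domain_terms, cap = 3, tokens = NULL) {
  if (is.character(domain_terms))
    domain_terms <- stats::setNames(rep(1, length(domain_terms)), domain_terms)
  if (length(domain_terms) == 0L) stop("empty term domain", call. = FALSE)
  stopifnot(all(domain_terms > 0), cap >= 1)
  if (is.null(tokens)) tokens <- tokenize(text)
  phrases <- strsplit(normalize_text(names(domain_terms)), " ", fixed = TRUE)
  cov <- vapply(phrases, function(p)
    min(count_phrase(tokens, p, cap), cap) / cap, numeric(1))
  sum(domain_terms * cov) / sum(domain_terms)
}

#' Combined keyword score across the three taxonomy domains
#'
#' Weighted mean of the AI, legal/regulatory and biomedical domain scores
#' (default equal weights), bounded in `[0, 1]`. This is the
#' `ai_keyword_combined_score` consumed by the ensemble classifier.
#'
#' @param text document text.
#' @param tax a `regfed_taxonomy`.
#' @param domain_weights three non-negative weights (AI, legal/regulatory,
#'   biomedical), not all zero.
#' @param cap saturation cap passed to [keyword_domain_score()].
#' @param tokens optional pre-tokenized text.
#' @return score in `[0, 1]`.
#' @export
combined_keyword_score <- function(text, tax, domain_weights = c(1, 1, 1),
                                   cap = 3, tokens = NULL) {
  stopifnot(inherits(tax, "regfed_taxonomy"), length(domain_weights) == 3L,
            all(domain_weights >= 0))
  if (sum(domain_weights) == 0) stop("domain weights must not all be zero",
                                     call. = FALSE)
  if (is.null(tokens)) tokens <- tokenize(text)
  s <- c(keyword_domain_score(tokens = tokens, text = NULL,
                              domain_terms = tax$ai_terms, cap = cap),
         keyword_domain_score(tokens = tokens, text = NULL,
                              domain_terms = tax$legal_regulatory_terms, cap = cap),
         keyword_domain_score(tokens = tokens, text = NULL,
                              domain_terms = tax$biomedical_terms, cap = cap))
  sum(domain_weights * s) / sum(domain_weights)
}

#' Score every document in a corpus
#'
#' Produces the full per-document score table the classifier consumes:
#' embedding similarities to the reference set (`avg_ref_score`,
#' `max_ref_score`, `ideal_score`) and keyword scores (`kw_ai`, `kw_legal`,
#' `kw_biomed`, `ai_keyword_combined_score`). Deterministic given a
#' deterministic backend, and order-independent: each row depends only on
#' its own document.
#'
#' @param x a `regfed_corpus`.
#' @param refs a [reference_set()].
#' @param cap keyword saturation cap.
#' @param domain_weights weights for [combined_keyword_score()].
#' @return data frame (class `regfed_scores`) keyed by `doc_id`.
#' @export
score_corpus <- function(x, refs, cap = 3, domain_weights = c(1, 1, 1)) {
  stopifnot(inherits(x, "regfed_corpus"), inherits(refs, "regfed_reference_set"))
  tax <- refs$taxonomy
  emb <- embed_texts(x$text, refs$backend)
  sims <- emb %*% t(refs$real_emb)             # n_docs x n_refs
  ideal <- as.numeric(emb %*% refs$ideal_emb)
  toks <- tokenize_many(x$text)
  kw <- vapply(toks, function(tk) c(
    keyword_domain_score(tokens = tk, text = NULL, domain_terms = tax$ai_terms,
                         cap = cap),
    keyword_domain_score(tokens = tk, text = NULL,
                         domain_terms = tax$legal_regulatory_terms, cap = cap),
    keyword_domain_score(tokens = tk, text = NULL,
                         domain_terms = tax$biomedical_terms, cap = cap)
  ), numeric(3))
  w <- domain_weights / sum(domain_weights)
  out <- data.frame(
    doc_id = x$doc_id,
    avg_ref_score = rowMeans(sims),
    max_ref_score = apply(sims, 1L, max),
    ideal_score = ideal,
    kw_ai = kw[1L, ], kw_legal = kw[2L, ], kw_biomed = kw[3L, ],
    ai_keyword_combined_score = as.numeric(w %*% kw),
    stringsAsFactors = FALSE
  )
  attr(out, "backend") <- refs$backend$name
  attr(out, "reference_version") <- refs$version
  class(out) <- c("regfed_scores", "data.frame")
  out
}

#' Score names a threshold clause may reference
#' @return character vector of the four classifier score components.
#' @export
score_names <- function() {
  c("avg_ref_score", "max_ref_score", "ideal_score", "ai_keyword_combined_score")
}

#' Write / read a score table as JSON-lines
#'
#' @param scores a `regfed_scores` data frame.
#' @param path file path.
#' @return `path` (write) or the score table (read).
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "regfed_scores"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(scores)))
    writeLines(jsonlite::toJSON(as.list(scores[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  out <- do.call(rbind, rows)
  class(out) <- c("regfed_scores", "data.frame")
  out
}
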