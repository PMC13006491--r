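#' Deterministic hashed text-embedding backend
#'
#' The default embedding backend maps normalized tokens (and optionally
#' token n-grams) into a fixed number of buckets by feature hashing with a
#' sign hash, weights each feature by `log(1 + count)` and L2-normalizes the
#' result. It is fully deterministic, needs no model download, and respects
#' the backend contract: same text, same vector. Alternative backends (for
#' example transformer sentence embeddings) can be registered as any object
#' with class `regfed_backend` honouring the same contract.
#'
#' @param dim embedding dimensionality (number of hash buckets).
#' @param ngram integer vector of token n-gram orders to hash. The default
#'   (unigrams + bigrams) makes multi-token phrases distinctive features,
#'   which sharpens similarity contrast between topical content and
#'   boilerplate.
#' @param max_tokens documents are embedded on their first `max_tokens`
#'   tokens; longer tails are ignored.
#' @return an object of class `regfed_backend`.
#' @export
hash_backend <- function(dim = 1024L, ngram = 1:2, max_tokens = 5000L) {
  stopifnot(dim >= 2, all(ngram >= 1), max_tokens >= 1)
  structure(list(name = sprintf("hash-%d", dim), dim = as.integer(dim),
                 ngram = as.integer(ngram), max_tokens = as.integer(max_tokens),
                 deterministic = TRUE),
            class = "regfed_backend")
}

#' @export
print.regfed_backend <- function(x, ...) {
  cat(sprintf("<regfed_backend> %s (dim=%d, deterministic=%s)\n",
              x$name, x$dim, x$deterministic))
  invisible(x)
}

.doc_features <- function(tokens, backend) {
  tokens <- utils::head(tokens, backend$max_tokens)
  feats <- character(0)
  for (k in backend$ngram) {
    n <- length(tokens)
    if (n < k) next
    if (k == 1L) feats <- c(feats, tokens)
    else {
      grams <- tokens[1:(n - k + 1L)]
      for (j in 2:k) grams <- paste(grams, tokens[j:(n - k + j)], sep = "_")
      feats <- c(feats, grams)
    }
  }
  feats
}

#' Embed a single text
#'
#' Returns a unit-norm numeric vector of length `backend$dim`. Empty text
#' yields an all-zero vector flagged with attribute `empty = TRUE` — the
#' only case a non-unit vector is produced.
#'
#' @param text a character string.
#' @param backend a [hash_backend()].
#' @return numeric vector with attribute `empty`.
#' @export
embed <- function(text, backend = hash_backend()) {
  m <- embed_texts(text, backend)
  v <- m[1L, ]
  attr(v, "empty") <- attr(m, "empty")[1L]
  v
}

#' Embed many texts into a row matrix
#'
#' Vectorized form of [embed()]; row `i` is the embedding of `texts[i]`.
#' Rows for empty texts are all-zero and recorded in the `empty` attribute
#' (a logical vector).
#'
#' @param texts character vector.
#' @param backend a [hash_backend()].
#' @return numeric matrix, `length(texts)` x `backend$dim`, unit-norm rows.
#' @export
embed_texts <- function(texts, backend = hash_backend()) {
  stopifnot(inherits(backend, "regfed_backend"))
  tok <- tokenize_many(texts)
  featl <- lapply(tok, .doc_features, backend = backend)
  vocab <- unique(unlist(featl, use.names = FALSE))
  if (is.null(vocab)) vocab <- character(0)
  idx <- hash_bucket(vocab, backend$dim)      # bucket per vocabulary feature
  sgn <- hash_sign(vocab)
  key <- 2L * idx - (sgn > 0)                 # interleave bucket and sign

  n <- length(tok)
  out <- matrix(0, nrow = n, ncol = backend$dim)
  empty <- logical(n)
  nbins <- 2L * backend$dim
  for (i in seq_len(n)) {
    f <- featl[[i]]
    if (!length(f)) { empty[i] <- TRUE; next }
    cnt <- tabulate(key[match(f, vocab)], nbins = nbins)
    v <- log1p(cnt[seq(1L, nbins, 2L)]) - log1p(cnt[seq(2L, nbins, 2L)])
    nv <- sqrt(sum(v^2))
    if (nv > 0) out[i, ] <- v / nv else empty[i] <- TRUE
  }
  attr(out, "empty") <- empty
  attr(out, "backend") <- backend$name
  out
}

#' Cosine similarity between two embedding vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in `[-1, 1]`; 0 if either vector is all-zero.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("embedding dimension mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  s <- sum(a * b) / (na * nb)
  max(-1, min(1, s))
}
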