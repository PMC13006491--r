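#' Normalize free text for scoring
#'
#' Applies the package-wide normalization contract: Unicode NFKC folding,
#' lower-casing, replacement of every non-alphanumeric run by a single space.
#' All keyword matching and embedding tokenization operate on this normal
#' form, so scores are insensitive to case, punctuation and Unicode
#' compatibility variants.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[^a-z0-9]+", " ")
  stringi::stri_trim_both(x)
}

#' Tokenize normalized text
#'
#' Whitespace tokenization of [normalize_text()] output. Empty input yields a
#' zero-length token vector.
#'
#' @param x a single character string.
#' @return character vector of tokens.
#' @export
tokenize <- function(x) {
  stopifnot(length(x) == 1L)
  x <- normalize_text(x)
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1L]]
}

# Tokenize many texts at once; returns a list of token vectors.
tokenize_many <- function(x) {
  x <- normalize_text(x)
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

# Deterministic polynomial string hashes over UTF-8 bytes. Two independent
# moduli: one for the bucket index, one for the sign bit of feature hashing.
# Arithmetic stays far below 2^53 so results are exact in doubles.
.hash_poly <- function(strings, base, mod) {
  vapply(strings, function(s) {
    b <- utf8ToInt(enc2utf8(s))
    h <- 0
    for (v in b) h <- (h * base + v) %% mod
    h
  }, numeric(1), USE.NAMES = FALSE)
}

hash_bucket <- function(strings, dim) {
  .hash_poly(strings, base = 31, mod = 1048573) %% dim + 1L
}

hash_sign <- function(strings) {
  ifelse(.hash_poly(strings, base = 37, mod = 999983) %% 2 == 0, 1, -1)
}

# Short hex content digest used for snapshot/monitoring bookkeeping.
content_digest <- function(x) {
  x <- enc2utf8(x)
  h1 <- .hash_poly(x, base = 31, mod = 1048573)
  h2 <- .hash_poly(x, base = 131, mod = 999999937)
  sprintf("%05x%08x", as.integer(h1), as.integer(h2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
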