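#' Keyword taxonomy over three terminology domains
#'
#' A taxonomy carries exactly three named term lists — AI, legal/regulatory
#' and biomedical terminology — used both for keyword scoring and to build
#' the synthetic "ideal" reference document. Terms are lower-case phrases of
#' one or more tokens; each may carry a positive weight (default 1).
#'
#' @param ai_terms,legal_regulatory_terms,biomedical_terms character vectors
#'   of terms, or named numeric vectors of weights (names are terms).
#' @return an object of class `regfed_taxonomy`.
#' @export
taxonomy <- function(ai_terms, legal_regulatory_terms, biomedical_terms) {
  mk <- function(x, domain) {
    if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
    stopifnot(is.numeric(x))
    if (length(x) == 0L) stop("empty taxonomy domain: ", domain, call. = FALSE)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("taxonomy terms must be named in domain ", domain, call. = FALSE)
    names(x) <- normalize_text(names(x))
    if (anyDuplicated(names(x)))
      stop("duplicate terms in domain ", domain, call. = FALSE)
    if (any(x <= 0)) stop("term weights must be positive in ", domain, call. = FALSE)
    x
  }
  structure(list(ai_terms = mk(ai_terms, "ai"),
                 legal_regulatory_terms = mk(legal_regulatory_terms, "legal_regulatory"),
                 biomedical_terms = mk(biomedical_terms, "biomedical")),
            class = "regfed_taxonomy")
}

#' Default keyword taxonomy
#'
#' A compact curated taxonomy of explicit AI/ML terminology, legal and
#' regulatory vocabulary, and biomedical vocabulary, suitable for triaging
#' English-language drug-regulatory text. Intended as a starting point;
#' production deployments are expected to extend it with
#' jurisdiction-specific terminology.
#'
#' @return a `regfed_taxonomy`.
#' @export
default_taxonomy <- function() {
  taxonomy(
    ai_terms = c(
      "artificial intelligence", "machine learning", "deep learning",
      "neural network", "natural language processing", "large language model",
      "algorithm", "algorithmic", "predictive model", "ai",
      "supervised learning", "unsupervised learning", "reinforcement learning",
      "training data", "model validation", "explainability",
      "generative model", "classifier", "feature engineering", "data science"
    ),
    legal_regulatory_terms = c(
      "regulation", "regulatory", "guidance", "compliance", "policy",
      "framework", "oversight", "legislation", "directive", "statute",
      "enforcement", "approval", "submission", "requirement", "standard",
      "accountability", "transparency", "governance", "audit", "conformity"
    ),
    biomedical_terms = c(
      "drug", "clinical trial", "pharmacovigilance", "therapeutic",
      "biologic", "patient", "medical device", "pharmaceutical", "safety",
      "efficacy", "manufacturing", "quality control", "diagnosis",
      "treatment", "adverse event", "clinical development", "biomarker",
      "dosage", "post market surveillance", "drug development"
    )
  )
}

#' Read a taxonomy from a plain-text file
#'
#' Format: three sections introduced by header lines `[ai]`,
#' `[legal_regulatory]`, `[biomedical]`; one term per line, with an optional
#' whitespace-separated trailing weight. Blank lines and `#` comments are
#' ignored.
#'
#' @param path file path.
#' @return a `regfed_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  domains <- list(ai = numeric(0), legal_regulatory = numeric(0),
                  biomedical = numeric(0))
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!cur %in% names(domains))
        stop("unknown taxonomy domain header: ", ln, call. = FALSE)
      next
    }
    if (is.null(cur)) stop("term before any domain header: ", ln, call. = FALSE)
    m <- regmatches(ln, regexec("^(.*?)\\s+([0-9.]+)$", ln))[[1L]]
    if (length(m) == 3L && !is.na(suppressWarnings(as.numeric(m[3L])))) {
      w <- as.numeric(m[3L]); term <- m[2L]
    } else {
      w <- 1; term <- ln
    }
    domains[[cur]] <- c(domains[[cur]], stats::setNames(w, term))
  }
  taxonomy(domains$ai, domains$legal_regulatory, domains$biomedical)
}

#' Write a taxonomy in the plain-text exchange format
#'
#' @param tax a `regfed_taxonomy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "regfed_taxonomy"))
  fmt <- function(x) ifelse(x == 1, names(x), sprintf("%s %g", names(x), x))
  lines <- c("[ai]", fmt(tax$ai_terms),
             "", "[legal_regulatory]", fmt(tax$legal_regulatory_terms),
             "", "[biomedical]", fmt(tax$biomedical_terms))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.regfed_taxonomy <- function(x, ...) {
  cat(sprintf("<regfed_taxonomy> ai=%d, legal_regulatory=%d, biomedical=%d terms\n",
              length(x$ai_terms), length(x$legal_regulatory_terms),
              length(x$biomedical_terms)))
  invisible(x)
}
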