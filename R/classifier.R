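#' OR-ensemble threshold configuration
#'
#' A configuration is a non-empty set of clauses, each pairing one score
#' component with an inclusive threshold; a document is classified
#' AI-relevant if *any* clause is met (`score >= threshold`). Inclusive
#' comparison matches the conventional printed form of such rules
#' (e.g. `ai_keyword_combined_score >= 0.33`).
#'
#' @param clauses named numeric vector: names are score components (see
#'   [score_names()]), values are thresholds.
#' @param label identifier for reports.
#' @return an object of class `regfed_threshold_config`.
#' @export
threshold_config <- function(clauses, label = NULL) {
  stopifnot(is.numeric(clauses), length(clauses) >= 1L)
  nm <- names(clauses)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every clause needs a score name", call. = FALSE)
  bad <- setdiff(nm, score_names())
  if (length(bad)) stop("unknown score component(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(nm)) stop("duplicate score name in clauses", call. = FALSE)
  if (any(!is.finite(clauses))) stop("thresholds must be finite", call. = FALSE)
  if (is.null(label))
    label <- paste(sprintf("%s>=%g", nm, clauses), collapse = " | ")
  structure(list(clauses = clauses, label = label),
            class = "regfed_threshold_config")
}

#' @export
print.regfed_threshold_config <- function(x, ...) {
  cat("<regfed_threshold_config>", x$label, "\n")
  invisible(x)
}

#' Classify a single score vector
#'
#' @param scores one-row `regfed_scores` data frame, or a named list/vector
#'   holding every score component the configuration references.
#' @param cfg a [threshold_config()].
#' @return `TRUE` iff any clause's score meets its threshold (inclusive).
#' @export
classify <- function(scores, cfg) {
  stopifnot(inherits(cfg, "regfed_threshold_config"))
  nm <- names(cfg$clauses)
  vals <- vapply(nm, function(s) {
    v <- if (is.data.frame(scores)) scores[[s]] else scores[[s]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("missing score component: ", s, call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  any(vals >= cfg$clauses)
}

#' Classify a whole score table
#'
#' Applies the OR-ensemble rule to every document and reports the positive
#' rate plus per-clause trigger counts (how many positives each clause alone
#' would have caught). The positive set is, by construction, the union of
#' the per-clause positive sets.
#'
#' @param scores a `regfed_scores` data frame.
#' @param cfg a [threshold_config()].
#' @return object of class `regfed_classification`: list with `labels`
#'   (data frame `doc_id`, `label`, `clauses`), `positive_rate`,
#'   `n_positive`, `n_documents`, `clause_counts`, `config`. For an empty
#'   table the positive rate is reported as 0 with `undefined_rate = TRUE`.
#' @export
classify_corpus <- function(scores, cfg) {
  stopifnot(inherits(cfg, "regfed_threshold_config"))
  nm <- names(cfg$clauses)
  miss <- setdiff(nm, names(scores))
  if (length(miss)) stop("missing score component(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(scores)
  hit <- matrix(FALSE, nrow = n, ncol = length(nm), dimnames = list(NULL, nm))
  for (s in nm) hit[, s] <- scores[[s]] >= cfg$clauses[[s]]
  label <- if (n) apply(hit, 1L, any) else logical(0)
  trig <- if (n) apply(hit, 1L, function(h) paste(nm[h], collapse = "+")) else
    character(0)
  structure(list(
    labels = data.frame(doc_id = scores$doc_id %||% character(0), label = label,
                        clauses = trig, stringsAsFactors = FALSE),
    positive_rate = if (n) sum(label) / n else 0,
    undefined_rate = n == 0L,
    n_positive = sum(label),
    n_documents = n,
    clause_counts = colSums(hit),
    config = cfg
  ), class = "regfed_classification")
}

#' @export
print.regfed_classification <- function(x, ...) {
  cat(sprintf("<regfed_classification> %s\n  %d/%d positive (%.2f%%)\n",
              x$config$label, x$n_positive, x$n_documents,
              100 * x$positive_rate))
  invisible(x)
}

#' Enumerate the default scoring-configuration templates
#'
#' The seven default templates: one single-clause template per score
#' component (average reference similarity, maximum reference similarity,
#' ideal-document similarity, combined keyword score) and the three OR-pairs
#' combining the keyword score with each similarity score. Thresholds are
#' unbound (`NA`) — the grid-search optimizer fills them in.
#'
#' @param available character vector of usable score names.
#' @return list of template objects: each a list with `score_names` and
#'   `label`.
#' @export
enumerate_configurations <- function(available = score_names()) {
  singles <- lapply(available, function(s) list(score_names = s, label = s))
  kw <- "ai_keyword_combined_score"
  pairs <- list()
  if (kw %in% available)
    pairs <- lapply(setdiff(available, kw), function(s)
      list(score_names = c(kw, s), label = paste(kw, "|", s)))
  c(singles, pairs)
}

#' Write classification labels as JSON-lines
#'
#' One record per document: `doc_id`, `label`, and the clauses that
#' triggered.
#'
#' @param result a `regfed_classification`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(result, path) {
  stopifnot(inherits(result, "regfed_classification"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  lab <- result$labels
  for (i in seq_len(nrow(lab)))
    writeLines(jsonlite::toJSON(list(doc_id = lab$doc_id[i],
                                     label = lab$label[i],
                                     clauses = lab$clauses[i]),
                                auto_unbox = TRUE), con, useBytes = TRUE)
  invisible(path)
}
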