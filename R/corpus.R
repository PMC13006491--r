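#' Construct a document corpus
#'
#' A corpus is a data frame with one row per regulatory document and a fixed
#' column contract: `doc_id`, `agency`, `url`, `title`, `date`, `language`,
#' `category`, `text`, `unextractable`. Dates may be `NA` (unknown); `text`
#' may be empty only when `unextractable` is `TRUE`.
#'
#' @param documents data frame carrying at least `doc_id` and `text`; missing
#'   metadata columns are filled with `NA`/defaults.
#' @param provenance free-text description of where the documents came from.
#' @return an object of class `regfed_corpus` (a data frame).
#' @export
corpus <- function(documents, provenance = "unspecified") {
  stopifnot(is.data.frame(documents))
  n <- nrow(documents)
  cols <- list(
    doc_id = as.character(documents$doc_id %||% character(0)),
    agency = as.character(documents$agency %||% rep("OTHER", n)),
    url = as.character(documents$url %||% rep(NA_character_, n)),
    title = as.character(documents$title %||% rep(NA_character_, n)),
    date = as.Date(documents$date %||% rep(NA, n)),
    language = as.character(documents$language %||% rep(NA_character_, n)),
    category = as.character(documents$category %||% rep(NA_character_, n)),
    text = as.character(documents$text %||% rep("", n)),
    unextractable = as.logical(documents$unextractable %||% rep(FALSE, n))
  )
  out <- data.frame(cols, stringsAsFactors = FALSE)
  validate_corpus(out)
  attr(out, "provenance") <- provenance
  class(out) <- c("regfed_corpus", "data.frame")
  out
}

validate_corpus <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$doc_id) || any(!nzchar(x$doc_id)))
    stop("every document needs a non-empty doc_id", call. = FALSE)
  dup <- unique(x$doc_id[duplicated(x$doc_id)])
  if (length(dup))
    stop("duplicate doc_id in corpus: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  bad <- !is.na(x$text) & !nzchar(x$text) & !x$unextractable
  if (any(bad))
    stop("empty text without unextractable flag: ",
         paste(utils::head(x$doc_id[bad], 5L), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @export
print.regfed_corpus <- function(x, ...) {
  cat(sprintf("<regfed_corpus> %d documents (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unspecified"))
  if (nrow(x)) {
    tab <- table(x$agency)
    cat("  agencies:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a corpus from a JSON-lines file
#'
#' One JSON object per line with the document fields. Malformed lines are
#' collected into an error report (attribute `"errors"`, a data frame of line
#' numbers and messages) rather than silently dropped; a duplicated `doc_id`
#' is a fatal error naming the id.
#'
#' @param path path to a `.jsonl` file.
#' @param provenance optional provenance label; defaults to the path.
#' @return a `regfed_corpus`; malformed-line report in `attr(x, "errors")`.
#' @export
load_corpus <- function(path, provenance = path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  errs <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) e)
    if (inherits(rec, "error") || is.null(rec$doc_id) || !nzchar(rec$doc_id %||% "")) {
      msg <- if (inherits(rec, "error")) conditionMessage(rec) else "missing doc_id"
      errs[[length(errs) + 1L]] <- data.frame(line = i, message = msg)
      next
    }
    recs[[i]] <- data.frame(
      doc_id = rec$doc_id,
      agency = rec$agency %||% "OTHER",
      url = rec$url %||% NA_character_,
      title = rec$title %||% NA_character_,
      date = rec$date %||% NA_character_,
      language = rec$language %||% NA_character_,
      category = rec$category %||% NA_character_,
      text = rec$text %||% "",
      unextractable = isTRUE(rec$unextractable),
      stringsAsFactors = FALSE
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(doc_id = character(0), text = character(0))
  df$date <- as.Date(df$date %||% character(0))
  out <- corpus(df, provenance = provenance)
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(0), message = character(0))
  out
}

#' Write a corpus as JSON-lines
#'
#' Inverse of [load_corpus()]: one JSON object per document, field order and
#' document order preserved, so a write/read cycle round-trips.
#'
#' @param x a `regfed_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "regfed_corpus"))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    rec <- list(
      doc_id = x$doc_id[i], agency = x$agency[i], url = x$url[i],
      title = x$title[i],
      date = if (is.na(x$date[i])) NULL else format(x$date[i]),
      language = x$language[i], category = x$category[i],
      text = x$text[i], unextractable = x$unextractable[i]
    )
    rec <- rec[!vapply(rec, function(v) is.null(v) || (length(v) == 1L && is.na(v)),
                       logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Filter configuration for corpus funnelling
#'
#' Defaults mirror the study window: publications from 2019-01-01 through
#' 2025-07-31, English only, with categorically unrelated content (routine
#' labels, administrative notices, standard pharmacovigilance reports)
#' excluded. Unknown dates are kept by default because agency timestamps can
#' reflect technical rather than content updates; unknown languages are
#' dropped by default.
#'
#' @param date_min,date_max inclusive date window (Date or `"YYYY-MM-DD"`).
#' @param allowed_languages character vector of language codes to keep.
#' @param excluded_categories categories to drop.
#' @param keep_unknown_date,keep_unknown_language how to treat missing
#'   metadata.
#' @return an object of class `regfed_filter_config`.
#' @export
filter_config <- function(date_min = "2019-01-01", date_max = "2025-07-31",
                          allowed_languages = "en",
                          excluded_categories = c("drug label",
                                                  "administrative notice",
                                                  "pharmacovigilance report"),
                          keep_unknown_date = TRUE,
                          keep_unknown_language = FALSE) {
  date_min <- as.Date(date_min)
  date_max <- as.Date(date_max)
  stopifnot(!is.na(date_min), !is.na(date_max), date_min <= date_max)
  structure(list(date_min = date_min, date_max = date_max,
                 allowed_languages = as.character(allowed_languages),
                 excluded_categories = as.character(excluded_categories),
                 keep_unknown_date = isTRUE(keep_unknown_date),
                 keep_unknown_language = isTRUE(keep_unknown_language)),
            class = "regfed_filter_config")
}

#' Apply funnel filters to a corpus
#'
#' Filters are applied in a fixed stage order — language first, then the
#' combined time + category stage — and a per-agency funnel report is
#' accumulated with counts and percentages relative to each agency's initial
#' collection. Every excluded document is attributed to exactly one exclusion
#' reason (the first failing criterion in stage order); the attribution table
#' is attached to the returned corpus as `attr(x, "exclusions")`.
#'
#' @param x a `regfed_corpus`.
#' @param cfg a [filter_config()].
#' @return list with elements `corpus` (the surviving documents) and
#'   `funnel` (a `regfed_funnel` data frame).
#' @export
apply_filters <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "regfed_corpus"), inherits(cfg, "regfed_filter_config"))
  agencies <- unique(x$agency)

  lang_ok <- ifelse(is.na(x$language), cfg$keep_unknown_language,
                    x$language %in% cfg$allowed_languages)
  date_ok <- ifelse(is.na(x$date), cfg$keep_unknown_date,
                    x$date >= cfg$date_min & x$date <= cfg$date_max)
  cat_ok <- is.na(x$category) | !(x$category %in% cfg$excluded_categories)

  reason <- rep(NA_character_, nrow(x))
  reason[!lang_ok] <- "language"
  reason[is.na(reason) & !date_ok] <- "date"
  reason[is.na(reason) & !cat_ok] <- "category"
  keep <- is.na(reason)

  stage1 <- lang_ok                      # after language filter
  stage2 <- lang_ok & date_ok & cat_ok   # after time + content filter

  rows <- list()
  for (ag in agencies) {
    sel <- x$agency == ag
    n0 <- sum(sel)
    rows[[length(rows) + 1L]] <- data.frame(
      agency = ag,
      stage = c("Initial collection", "Language filter", "Time & Content filter"),
      count = c(n0, sum(sel & stage1), sum(sel & stage2)),
      stringsAsFactors = FALSE
    )
  }
  rows[[length(rows) + 1L]] <- data.frame(
    agency = "Total",
    stage = c("Initial collection", "All filters"),
    count = c(nrow(x), sum(stage2)),
    stringsAsFactors = FALSE
  )
  funnel <- do.call(rbind, rows)
  initial <- funnel$count[match(funnel$agency,
                                funnel$agency[funnel$stage == "Initial collection"])]
  funnel$percent <- ifelse(initial > 0, 100 * funnel$count / initial,
                           ifelse(funnel$count == 0, 100, NA_real_))
  class(funnel) <- c("regfed_funnel", "data.frame")

  out <- x[keep, , drop = FALSE]
  attr(out, "provenance") <- paste0(attr(x, "provenance") %||% "", " [filtered]")
  class(out) <- class(x)
  attr(out, "exclusions") <- data.frame(doc_id = x$doc_id[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  list(corpus = out, funnel = funnel)
}

#' Append a classification stage to a funnel report
#'
#' Adds per-agency (and total) positive counts from a classification result
#' as an extra funnel stage, with percentages still relative to each agency's
#' initial collection.
#'
#' @param funnel a `regfed_funnel` from [apply_filters()].
#' @param result a `regfed_classification` from [classify_corpus()].
#' @param x the classified `regfed_corpus` (supplies agency tags).
#' @param stage label for the new stage.
#' @return the extended funnel report.
#' @export
funnel_add_classification <- function(funnel, result, x,
                                      stage = "AI classification") {
  stopifnot(inherits(funnel, "regfed_funnel"),
            inherits(result, "regfed_classification"),
            inherits(x, "regfed_corpus"))
  pos <- result$labels$doc_id[result$labels$label]
  init <- funnel[funnel$stage == "Initial collection", ]
  rows <- lapply(seq_len(nrow(init)), function(i) {
    ag <- init$agency[i]
    n <- if (ag == "Total") sum(x$doc_id %in% pos) else
      sum(x$doc_id %in% pos & x$agency == ag)
    data.frame(agency = ag, stage = stage, count = n,
               percent = if (init$count[i] > 0) 100 * n / init$count[i] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- rbind(as.data.frame(funnel), do.call(rbind, rows))
  ord <- order(match(out$agency, init$agency))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regfed_funnel", "data.frame")
  out
}

#' Write a funnel report as a delimited table
#'
#' Tab-separated columns `Agency | Filter Stage | Count | %`, percentages
#' rounded to one decimal for display (counts stay exact).
#'
#' @param funnel a `regfed_funnel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_funnel_report <- function(funnel, path) {
  stopifnot(inherits(funnel, "regfed_funnel"))
  df <- data.frame(Agency = funnel$agency, `Filter Stage` = funnel$stage,
                   Count = funnel$count,
                   `%` = sprintf("%.1f", funnel$percent),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a funnel report written by [write_funnel_report()]
#'
#' @param path file path.
#' @return a `regfed_funnel` data frame (percentages at one-decimal display
#'   precision).
#' @export
read_funnel_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "numeric")[seq_len(4)])
  out <- data.frame(agency = df$Agency, stage = df$`Filter Stage`,
                    count = df$Count, percent = df$`%`,
                    stringsAsFactors = FALSE)
  class(out) <- c("regfed_funnel", "data.frame")
  out
}
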