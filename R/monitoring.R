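#' Sitemap snapshot
#'
#' A point-in-time listing of source URLs with last-modified timestamps and
#' optional content digests, used to detect new and updated documents by
#' diffing two snapshots of the same source. Snapshots are local files or
#' data frames — no network access is involved.
#'
#' @param entries data frame with columns `url`, `last_modified` and
#'   optionally `digest`.
#' @param source label of the originating source (e.g. agency site).
#' @param taken_at timestamp of the snapshot.
#' @return an object of class `regfed_snapshot`.
#' @export
snapshot <- function(entries, source = "unknown", taken_at = Sys.time()) {
  stopifnot(is.data.frame(entries), all(c("url", "last_modified") %in%
                                          names(entries)))
  if (anyDuplicated(entries$url))
    stop("duplicate urls in snapshot", call. = FALSE)
  if (is.null(entries$digest)) entries$digest <- NA_character_
  entries <- entries[, c("url", "last_modified", "digest")]
  entries$url <- as.character(entries$url)
  entries$last_modified <- as.character(entries$last_modified)
  entries$digest <- as.character(entries$digest)
  structure(list(entries = entries, source = source,
                 taken_at = format(taken_at)),
            class = "regfed_snapshot")
}

#' Read / write a snapshot as JSON-lines
#'
#' First line is a header record (`source`, `taken_at`), then one record per
#' URL.
#'
#' @param x a [snapshot()].
#' @param path file path.
#' @return `path` (write) or a `regfed_snapshot` (read).
#' @export
write_snapshot <- function(x, path) {
  stopifnot(inherits(x, "regfed_snapshot"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(source = x$source, taken_at = x$taken_at),
                              auto_unbox = TRUE), con, useBytes = TRUE)
  for (i in seq_len(nrow(x$entries))) {
    rec <- as.list(x$entries[i, ])
    if (is.na(rec$digest)) rec$digest <- NULL
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- jsonlite::fromJSON(lines[[1L]])
  rows <- lapply(lines[-1L], function(l) {
    r <- jsonlite::fromJSON(l)
    data.frame(url = r$url, last_modified = r$last_modified,
               digest = r$digest %||% NA_character_, stringsAsFactors = FALSE)
  })
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(url = character(0), last_modified = character(0),
               digest = character(0), stringsAsFactors = FALSE)
  snapshot(entries, source = hdr$source, taken_at = hdr$taken_at)
}

#' Diff two snapshots of the same source
#'
#' @param old,new `regfed_snapshot` objects with matching `source`.
#' @return list of three disjoint character vectors: `new_urls` (in `new`
#'   only), `updated_urls` (in both, with changed `last_modified` or
#'   digest), `removed_urls` (in `old` only).
#' @export
diff_snapshots <- function(old, new) {
  stopifnot(inherits(old, "regfed_snapshot"), inherits(new, "regfed_snapshot"))
  if (!identical(old$source, new$source))
    stop("cannot diff snapshots from different sources: ", old$source,
         " vs ", new$source, call. = FALSE)
  ou <- old$entries$url; nu <- new$entries$url
  new_urls <- setdiff(nu, ou)
  removed_urls <- setdiff(ou, nu)
  common <- intersect(ou, nu)
  oi <- match(common, ou); ni <- match(common, nu)
  changed <- old$entries$last_modified[oi] != new$entries$last_modified[ni]
  dig_old <- old$entries$digest[oi]; dig_new <- new$entries$digest[ni]
  dig_changed <- !is.na(dig_old) & !is.na(dig_new) & dig_old != dig_new
  updated_urls <- common[changed | dig_changed]
  list(new_urls = new_urls, updated_urls = updated_urls,
       removed_urls = removed_urls)
}

#' Initialize an empty monitoring state
#'
#' The state tracks every document the monitor has seen (id, url, digest,
#' last scoring date), an append-only classification ledger (old labels are
#' never overwritten — updated documents get a new ledger entry), and the
#' per-batch history of new-document counts and positive rates.
#'
#' @return an object of class `regfed_monitor_state`.
#' @export
monitor_state <- function() {
  structure(list(
    known = data.frame(doc_id = character(0), url = character(0),
                       digest = character(0), last_scored = character(0),
                       label = logical(0), stringsAsFactors = FALSE),
    ledger = data.frame(doc_id = character(0), event = character(0),
                        label = logical(0), batch = integer(0),
                        timestamp = character(0), stringsAsFactors = FALSE),
    batches = data.frame(batch = integer(0), timestamp = character(0),
                         n_new = integer(0), n_positive = integer(0),
                         positive_rate = numeric(0), stringsAsFactors = FALSE)
  ), class = "regfed_monitor_state")
}

#' @export
print.regfed_monitor_state <- function(x, ...) {
  cat(sprintf("<regfed_monitor_state> %d known documents, %d ledger entries, %d batches\n",
              nrow(x$known), nrow(x$ledger), nrow(x$batches)))
  invisible(x)
}

#' Persist / restore monitoring state
#'
#' State is stored in a directory as three JSON files, written atomically
#' (temp file + rename) so a failed write never corrupts existing state.
#'
#' @param state a `regfed_monitor_state`.
#' @param dir state directory (created if missing).
#' @return `dir` (write) or a `regfed_monitor_state` (read).
#' @export
write_monitor_state <- function(state, dir) {
  stopifnot(inherits(state, "regfed_monitor_state"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (part in c("known", "ledger", "batches")) {
    tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
    jsonlite::write_json(state[[part]], tmp, dataframe = "rows", digits = NA)
    file.rename(tmp, file.path(dir, paste0(part, ".json")))
  }
  invisible(dir)
}

#' @rdname write_monitor_state
#' @export
read_monitor_state <- function(dir) {
  state <- monitor_state()
  for (part in c("known", "ledger", "batches")) {
    f <- file.path(dir, paste0(part, ".json"))
    if (!file.exists(f)) stop("missing state file: ", f, call. = FALSE)
    df <- jsonlite::fromJSON(f)
    if (length(df)) state[[part]] <- as.data.frame(df)
  }
  state
}

#' Classification pipeline bundle
#'
#' Bundles the components needed to score and classify a batch: reference
#' set, threshold configuration (the taxonomy and backend travel inside the
#' reference set). Validated up front so [incremental_update()] can fail
#' before touching any state.
#'
#' @param refs a [reference_set()].
#' @param config a [threshold_config()].
#' @param cap keyword saturation cap.
#' @param domain_weights keyword domain weights.
#' @return an object of class `regfed_pipeline`.
#' @export
classification_pipeline <- function(refs, config, cap = 3,
                                    domain_weights = c(1, 1, 1)) {
  if (!inherits(refs, "regfed_reference_set"))
    stop("pipeline component missing or invalid: reference set", call. = FALSE)
  if (!inherits(config, "regfed_threshold_config"))
    stop("pipeline component missing or invalid: threshold config", call. = FALSE)
  structure(list(refs = refs, config = config, cap = cap,
                 domain_weights = domain_weights),
            class = "regfed_pipeline")
}

#' Score and classify one batch of new/updated documents
#'
#' Scores and classifies only the batch, appends the outcomes to the ledger
#' and batch history, and leaves previously classified documents untouched
#' unless they are re-presented as updated (changed digest), in which case
#' they are re-scored and both old and new labels remain in the ledger.
#' Documents already known with an unchanged digest are skipped, so applying
#' the same batch twice is a no-op. The input state is never mutated — a new
#' state is returned (persist it with [write_monitor_state()], which is
#' atomic).
#'
#' @param state a `regfed_monitor_state`.
#' @param batch a `regfed_corpus` of new or updated documents.
#' @param pipeline a [classification_pipeline()].
#' @param timestamp batch timestamp label.
#' @return list: `state` (updated copy) and `report` (`batch`, `n_new`,
#'   `n_positive`, `positive_rate`, `rate_defined`).
#' @export
incremental_update <- function(state, batch, pipeline,
                               timestamp = format(Sys.time())) {
  stopifnot(inherits(state, "regfed_monitor_state"),
            inherits(batch, "regfed_corpus"))
  if (!inherits(pipeline, "regfed_pipeline"))
    stop("pipeline component missing or invalid", call. = FALSE)
  batch_no <- if (nrow(state$batches)) max(state$batches$batch) + 1L else 1L

  dig <- content_digest(batch$text)
  known_idx <- match(batch$doc_id, state$known$doc_id)
  is_new <- is.na(known_idx)
  is_updated <- !is_new & state$known$digest[known_idx] != dig
  process <- is_new | is_updated

  n_proc <- sum(process)
  if (n_proc == 0L) {
    report <- list(batch = batch_no, n_new = 0L, n_positive = 0L,
                   positive_rate = NA_real_, rate_defined = FALSE)
    return(list(state = state, report = report))
  }

  sub <- batch[process, , drop = FALSE]
  class(sub) <- class(batch)
  scores <- score_corpus(sub, pipeline$refs, cap = pipeline$cap,
                         domain_weights = pipeline$domain_weights)
  res <- classify_corpus(scores, pipeline$config)
  lab <- res$labels

  new_known <- data.frame(doc_id = sub$doc_id, url = sub$url,
                          digest = dig[process], last_scored = timestamp,
                          label = lab$label, stringsAsFactors = FALSE)
  known <- state$known
  known <- known[!(known$doc_id %in% sub$doc_id), , drop = FALSE]
  known <- rbind(known, new_known)
  rownames(known) <- NULL

  ledger_add <- data.frame(
    doc_id = sub$doc_id,
    event = ifelse(is_updated[process], "updated", "new"),
    label = lab$label, batch = batch_no, timestamp = timestamp,
    stringsAsFactors = FALSE
  )
  state$known <- known
  state$ledger <- rbind(state$ledger, ledger_add)
  state$batches <- rbind(state$batches, data.frame(
    batch = batch_no, timestamp = timestamp, n_new = n_proc,
    n_positive = res$n_positive, positive_rate = res$n_positive / n_proc,
    stringsAsFactors = FALSE))
  report <- list(batch = batch_no, n_new = n_proc,
                 n_positive = res$n_positive,
                 positive_rate = res$n_positive / n_proc, rate_defined = TRUE)
  list(state = state, report = report)
}

#' Current labels held by a monitoring state
#'
#' @param state a `regfed_monitor_state`.
#' @return data frame `doc_id`, `label` (latest label per document).
#' @export
monitor_labels <- function(state) {
  stopifnot(inherits(state, "regfed_monitor_state"))
  data.frame(doc_id = state$known$doc_id, label = state$known$label,
             stringsAsFactors = FALSE)
}
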