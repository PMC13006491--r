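#' Decision-boundary region around a threshold
#'
#' A boundary region collects documents whose score lies within a window
#' around a clause threshold — where classification uncertainty is highest.
#' Two window modes are defined: `narrow` uses an absolute half-width of
#' 0.01; `wide` uses half a standard deviation of that score's corpus
#' distribution (population SD, consistent with [sigma_position()]).
#' Membership is inclusive at both edges.
#'
#' @param score_name one of [score_names()].
#' @param center the threshold the window is centred on.
#' @param mode `"narrow"` or `"wide"`.
#' @param scores score table used to estimate the score SD (required for
#'   `mode = "wide"`).
#' @param narrow_half_width absolute half-width of the narrow window.
#' @return an object of class `regfed_boundary_region`.
#' @export
boundary_region <- function(score_name, center, mode = c("narrow", "wide"),
                            scores = NULL, narrow_half_width = 0.01) {
  mode <- match.arg(mode)
  stopifnot(score_name %in% score_names(), is.finite(center))
  hw <- if (mode == "narrow") narrow_half_width else {
    if (is.null(scores)) stop("wide regions need a score table for the SD",
                              call. = FALSE)
    x <- scores[[score_name]]
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("degenerate score distribution: SD is zero", call. = FALSE)
    0.5 * s
  }
  stopifnot(hw > 0)
  # a tiny absolute tolerance keeps inclusive edges robust to binary
  # floating-point representation (e.g. |0.32 - 0.33| vs 0.01)
  structure(list(score_name = score_name, center = center, mode = mode,
                 half_width = hw, tol = 1e-9),
            class = "regfed_boundary_region")
}

#' Documents inside a boundary region
#'
#' @param scores a `regfed_scores` table.
#' @param region a [boundary_region()].
#' @return character vector of doc ids with
#'   `|score - center| <= half_width`.
#' @export
boundary_members <- function(scores, region) {
  stopifnot(inherits(region, "regfed_boundary_region"))
  x <- scores[[region$score_name]]
  if (is.null(x)) stop("score not present: ", region$score_name, call. = FALSE)
  scores$doc_id[abs(x - region$center) <= region$half_width + region$tol]
}

#' Boundary-region ensemble validation
#'
#' For every clause of the ensemble configuration and both window modes,
#' restricts the corpus to the boundary region around that clause's
#' threshold and compares each individual method against the full ensemble:
#' recall over the test-labeled documents in the region, positive rate over
#' all region members, and the ensemble-minus-method deltas in percentage
#' points. Regions containing no test-labeled documents get `NA` recalls,
#' flagged in `recall_defined`.
#'
#' @param scores a `regfed_scores` table.
#' @param ts a [test_set()].
#' @param ensemble_cfg the OR-ensemble [threshold_config()].
#' @param per_method_cfgs named list of single-method configurations to
#'   compare against; defaults to each ensemble clause on its own.
#' @param modes window modes to analyze.
#' @return data frame (class `regfed_boundary_report`) with one row per
#'   clause x mode x method.
#' @export
boundary_analysis <- function(scores, ts, ensemble_cfg, per_method_cfgs = NULL,
                              modes = c("narrow", "wide")) {
  stopifnot(inherits(ensemble_cfg, "regfed_threshold_config"),
            inherits(ts, "regfed_test_set"))
  if (is.null(per_method_cfgs)) {
    per_method_cfgs <- lapply(seq_along(ensemble_cfg$clauses), function(i)
      threshold_config(ensemble_cfg$clauses[i]))
    names(per_method_cfgs) <- names(ensemble_cfg$clauses)
  }
  ens_pos <- .positive_ids(classify_corpus(scores, ensemble_cfg))
  meth_pos <- lapply(per_method_cfgs, function(cfg)
    .positive_ids(classify_corpus(scores, cfg)))
  rows <- list()
  for (ci in seq_along(ensemble_cfg$clauses)) {
    sname <- names(ensemble_cfg$clauses)[ci]
    thr <- ensemble_cfg$clauses[[ci]]
    for (mode in modes) {
      region <- boundary_region(sname, thr, mode, scores = scores)
      members <- boundary_members(scores, region)
      rel_in <- intersect(members, ts$relevant_ids)
      n_rel <- length(rel_in)
      n_mem <- length(members)
      ens_recall <- if (n_rel) mean(rel_in %in% ens_pos) else NA_real_
      ens_pr <- if (n_mem) mean(members %in% ens_pos) else NA_real_
      for (mi in seq_along(meth_pos)) {
        mp <- meth_pos[[mi]]
        m_recall <- if (n_rel) mean(rel_in %in% mp) else NA_real_
        m_pr <- if (n_mem) mean(members %in% mp) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          boundary_score = sname, threshold = thr, mode = mode,
          half_width = region$half_width,
          method = names(meth_pos)[mi],
          n_docs = n_mem, n_test_relevant = n_rel,
          method_recall = m_recall, ensemble_recall = ens_recall,
          method_positive_rate = m_pr, ensemble_positive_rate = ens_pr,
          recall_delta_pp = 100 * (ens_recall - m_recall),
          positive_rate_delta_pp = 100 * (ens_pr - m_pr),
          recall_defined = n_rel > 0L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("regfed_boundary_report", "data.frame")
  out
}

#' Per-agency positive rates and bias audit
#'
#' Computes each agency's positive classification rate, the maximum absolute
#' pairwise gap, and all pairwise rate ratios. Agencies with zero documents
#' are omitted with a warning; with fewer than two agencies the gap is
#' flagged undefined.
#'
#' @param labels a `regfed_classification` or labels data frame.
#' @param x the classified `regfed_corpus` (supplies agency tags).
#' @return object of class `regfed_bias_report`: list with `rates` (data
#'   frame `agency`, `n`, `n_positive`, `positive_rate`), `max_gap`,
#'   `ratios` (data frame of agency pairs), `gap_defined`.
#' @export
per_agency_positive_rates <- function(labels, x) {
  stopifnot(inherits(x, "regfed_corpus"))
  lab <- if (inherits(labels, "regfed_classification")) labels$labels else labels
  idx <- match(lab$doc_id, x$doc_id)
  if (anyNA(idx)) stop("labeled documents missing from corpus: ",
                       paste(utils::head(lab$doc_id[is.na(idx)], 5L),
                             collapse = ", "), call. = FALSE)
  agency <- x$agency[idx]
  agencies <- unique(x$agency)
  absent <- setdiff(agencies, agency)
  if (length(absent))
    warning("agencies with no labeled documents omitted: ",
            paste(absent, collapse = ", "))
  rates <- do.call(rbind, lapply(unique(agency), function(ag) {
    sel <- agency == ag
    data.frame(agency = ag, n = sum(sel), n_positive = sum(lab$label[sel]),
               positive_rate = mean(lab$label[sel]), stringsAsFactors = FALSE)
  }))
  gap_defined <- nrow(rates) >= 2L
  max_gap <- if (gap_defined)
    max(abs(outer(rates$positive_rate, rates$positive_rate, "-"))) else NA_real_
  ratios <- NULL
  if (gap_defined) {
    cmb <- utils::combn(nrow(rates), 2L)
    ratios <- data.frame(
      agency_a = rates$agency[cmb[1L, ]], agency_b = rates$agency[cmb[2L, ]],
      rate_a = rates$positive_rate[cmb[1L, ]],
      rate_b = rates$positive_rate[cmb[2L, ]],
      gap = abs(rates$positive_rate[cmb[1L, ]] - rates$positive_rate[cmb[2L, ]]),
      ratio = ifelse(rates$positive_rate[cmb[2L, ]] > 0,
                     rates$positive_rate[cmb[1L, ]] /
                       rates$positive_rate[cmb[2L, ]], NA_real_),
      stringsAsFactors = FALSE
    )
  }
  structure(list(rates = rates, max_gap = max_gap, ratios = ratios,
                 gap_defined = gap_defined),
            class = "regfed_bias_report")
}

#' @export
print.regfed_bias_report <- function(x, ...) {
  cat("<regfed_bias_report>\n")
  for (i in seq_len(nrow(x$rates)))
    cat(sprintf("  %s: %d/%d positive (%.2f%%)\n", x$rates$agency[i],
                x$rates$n_positive[i], x$rates$n[i],
                100 * x$rates$positive_rate[i]))
  if (x$gap_defined) cat(sprintf("  max pairwise gap: %.2f pp\n", 100 * x$max_gap))
  invisible(x)
}

#' Diversify a reference set with new exemplar documents
#'
#' Appends new reference documents (for example, exemplars in an
#' under-detected agency's style) to an existing reference set, re-embedding
#' everything under the same backend, and records the provenance of the
#' additions. Any score table computed from the old set must be recomputed
#' — the returned set carries a bumped version label so stale score tables
#' are detectable via `attr(scores, "reference_version")`.
#'
#' @param refs a [reference_set()].
#' @param new_docs a `regfed_corpus` of additional exemplars; ids must be
#'   disjoint from the existing references.
#' @return the enlarged `regfed_reference_set`.
#' @export
diversify_references <- function(refs, new_docs) {
  stopifnot(inherits(refs, "regfed_reference_set"),
            inherits(new_docs, "regfed_corpus"))
  dup <- intersect(new_docs$doc_id, refs$real_docs$doc_id)
  if (length(dup)) stop("duplicate reference id(s): ",
                        paste(dup, collapse = ", "), call. = FALSE)
  strip <- function(d) { d <- as.data.frame(d); class(d) <- "data.frame"; d }
  combined <- corpus(rbind(strip(refs$real_docs), strip(new_docs)),
                     provenance = paste0(attr(refs$real_docs, "provenance"),
                                         " + ", attr(new_docs, "provenance")))
  out <- reference_set(combined, tax = refs$taxonomy, backend = refs$backend,
                       version = paste0(refs$version, "+",
                                        nrow(new_docs), "refs"))
  attr(out, "added_ids") <- new_docs$doc_id
  out
}
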