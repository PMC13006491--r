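#' Labeled test set for recall evaluation
#'
#' Holds the ids of documents known to be AI-relevant, with a
#' high-confidence subset. The default study shape is 127 relevant ids of
#' which 38 are high-confidence.
#'
#' @param relevant_ids character vector of AI-relevant doc ids.
#' @param high_confidence_ids subset of `relevant_ids`.
#' @return an object of class `regfed_test_set`.
#' @export
test_set <- function(relevant_ids, high_confidence_ids = character(0)) {
  relevant_ids <- unique(as.character(relevant_ids))
  high_confidence_ids <- unique(as.character(high_confidence_ids))
  if (!all(high_confidence_ids %in% relevant_ids))
    stop("high-confidence ids must be a subset of relevant ids", call. = FALSE)
  structure(list(relevant_ids = relevant_ids,
                 high_confidence_ids = high_confidence_ids),
            class = "regfed_test_set")
}

#' @export
print.regfed_test_set <- function(x, ...) {
  cat(sprintf("<regfed_test_set> %d relevant, %d high-confidence\n",
              length(x$relevant_ids), length(x$high_confidence_ids)))
  invisible(x)
}

.positive_ids <- function(labels) {
  if (inherits(labels, "regfed_classification")) labels <- labels$labels
  stopifnot(is.data.frame(labels))
  labels$doc_id[labels$label]
}

.all_ids <- function(labels) {
  if (inherits(labels, "regfed_classification")) labels <- labels$labels
  labels$doc_id
}

#' Test Recall
#'
#' Fraction of the test set's relevant documents labeled positive.
#'
#' @param labels a `regfed_classification` or its `labels` data frame.
#' @param ts a [test_set()].
#' @return recall in `[0, 1]`.
#' @export
test_recall <- function(labels, ts) {
  stopifnot(inherits(ts, "regfed_test_set"))
  ids <- .all_ids(labels)
  miss <- setdiff(ts$relevant_ids, ids)
  if (length(miss)) stop("test ids missing from labels: ",
                         paste(utils::head(miss, 5L), collapse = ", "),
                         call. = FALSE)
  mean(ts$relevant_ids %in% .positive_ids(labels))
}

#' High Priority Recall
#'
#' Recall restricted to the high-confidence subset of the test set.
#'
#' @inheritParams test_recall
#' @return recall in `[0, 1]`.
#' @export
high_priority_recall <- function(labels, ts) {
  stopifnot(inherits(ts, "regfed_test_set"))
  if (length(ts$high_confidence_ids) == 0L)
    stop("empty high-confidence set", call. = FALSE)
  ids <- .all_ids(labels)
  miss <- setdiff(ts$high_confidence_ids, ids)
  if (length(miss)) stop("test ids missing from labels: ",
                         paste(utils::head(miss, 5L), collapse = ", "),
                         call. = FALSE)
  mean(ts$high_confidence_ids %in% .positive_ids(labels))
}

#' Evaluate one threshold configuration
#'
#' @param scores a `regfed_scores` table covering the corpus and test set.
#' @param cfg a [threshold_config()].
#' @param ts a [test_set()].
#' @return list: `test_recall`, `high_priority_recall`, `positive_rate`,
#'   `config`.
#' @export
evaluate_config <- function(scores, cfg, ts) {
  res <- classify_corpus(scores, cfg)
  list(test_recall = test_recall(res, ts),
       high_priority_recall = high_priority_recall(res, ts),
       positive_rate = res$positive_rate,
       config = cfg)
}

#' Threshold grid specification
#'
#' @param grids named list of threshold vectors, one per score component; by
#'   default step 0.01 over `[0, 1]` for every component in [score_names()].
#' @param min_test_recall feasibility constraint on Test Recall (default
#'   0.70).
#' @return an object of class `regfed_grid_spec`.
#' @export
grid_spec <- function(grids = NULL, min_test_recall = 0.70) {
  if (is.null(grids))
    grids <- stats::setNames(rep(list(seq(0, 1, by = 0.01)), length(score_names())),
                             score_names())
  stopifnot(is.list(grids), length(grids) > 0)
  for (g in grids) {
    if (!length(g) || any(!is.finite(g))) stop("empty or non-finite grid",
                                               call. = FALSE)
  }
  grids <- lapply(grids, function(g) sort(unique(as.numeric(g))))
  structure(list(grids = grids, min_test_recall = min_test_recall),
            class = "regfed_grid_spec")
}

# Exact counts of {x >= t} for every grid threshold via findInterval:
# findInterval(x, g) = number of grid points <= x, so clause "x >= g[i]"
# holds iff i <= findInterval(x, g).
.grid_rank <- function(x, g) findInterval(x, g)

# Metrics for a single-clause template on one grid: counts of surviving
# documents / relevant / high-confidence at every threshold.
.single_counts <- function(rank_vec, m) {
  # number of docs with rank >= i, for i in 1..m
  cnt <- tabulate(rank_vec + 1L, nbins = m + 1L)  # ranks 0..m
  rev(cumsum(rev(cnt)))[-1L]                      # drop rank-0 bucket
}

# 2-D cumulative count of (rank1 < i, rank2 < j) pairs; used for OR-pairs:
# a doc is negative at (t1, t2) iff it fails both clauses.
.pair_neg_counts <- function(r1, r2, m1, m2) {
  M <- matrix(0, nrow = m1 + 1L, ncol = m2 + 1L)
  tab <- table(factor(r1, levels = 0:m1), factor(r2, levels = 0:m2))
  M[] <- tab
  M <- apply(M, 2L, cumsum)
  M <- t(apply(M, 1L, cumsum))
  M  # M[i+1, j+1] = #docs with rank1 <= i and rank2 <= j
}

.template_metrics <- function(scores, ts, snames, grids) {
  n <- nrow(scores)
  rel <- match(ts$relevant_ids, scores$doc_id)
  hig <- match(ts$high_confidence_ids, scores$doc_id)
  if (anyNA(rel) || anyNA(hig))
    stop("test ids missing from score table", call. = FALSE)
  rr <- function(cnt, tot) if (tot) cnt / tot else NA_real_
  k <- length(snames)
  if (k == 1L) {
    g <- grids[[snames]]
    m <- length(g)
    r <- .grid_rank(scores[[snames]], g)
    pos <- .single_counts(r, m)
    relc <- .single_counts(r[rel], m)
    higc <- .single_counts(r[hig], m)
    data.frame(score_1 = snames, thr_1 = g,
               score_2 = NA_character_, thr_2 = NA_real_,
               n_clauses = 1L,
               test_recall = rr(relc, length(rel)),
               high_priority_recall = rr(higc, length(hig)),
               positive_rate = pos / n,
               stringsAsFactors = FALSE)
  } else if (k == 2L) {
    g1 <- grids[[snames[1L]]]; g2 <- grids[[snames[2L]]]
    m1 <- length(g1); m2 <- length(g2)
    r1 <- .grid_rank(scores[[snames[1L]]], g1)
    r2 <- .grid_rank(scores[[snames[2L]]], g2)
    neg <- .pair_neg_counts(r1, r2, m1, m2)
    negr <- .pair_neg_counts(r1[rel], r2[rel], m1, m2)
    negh <- .pair_neg_counts(r1[hig], r2[hig], m1, m2)
    ij <- expand.grid(i = seq_len(m1), j = seq_len(m2))
    nneg <- neg[cbind(ij$i, ij$j)]       # docs with rank1 < i and rank2 < j
    nnegr <- negr[cbind(ij$i, ij$j)]
    nnegh <- negh[cbind(ij$i, ij$j)]
    data.frame(score_1 = snames[1L], thr_1 = g1[ij$i],
               score_2 = snames[2L], thr_2 = g2[ij$j],
               n_clauses = 2L,
               test_recall = rr(length(rel) - nnegr, length(rel)),
               high_priority_recall = rr(length(hig) - nnegh, length(hig)),
               positive_rate = (n - nneg) / n,
               stringsAsFactors = FALSE)
  } else {
    stop("templates with more than two clauses are not supported by the ",
         "ranking schema", call. = FALSE)
  }
}

#' Recall-constrained threshold grid search
#'
#' Evaluates every configuration template at every grid point, keeps the
#' configurations whose Test Recall meets the feasibility constraint, and
#' ranks them by ascending Positive Rate. Ties are broken by higher High
#' Priority Recall, then higher Test Recall, then fewer clauses, then a
#' deterministic lexicographic key on clause names and thresholds so the
#' ranking is reproducible regardless of enumeration order.
#'
#' @param scores a `regfed_scores` table for the full corpus.
#' @param ts a [test_set()]; all test ids must be scored.
#' @param templates configuration templates as produced by
#'   [enumerate_configurations()]. Defaults to the single OR-pair of the
#'   combined keyword score with the average reference similarity plus each
#'   of those scores alone.
#' @param grid a [grid_spec()].
#' @return object of class `regfed_grid_search`: list with `ranking` (data
#'   frame of feasible configurations, best first), `n_evaluated`,
#'   `min_test_recall`, `feasible`. An infeasible constraint yields an empty
#'   ranking with a warning, not an error.
#' @export
grid_search <- function(scores, ts, templates = enumerate_configurations(),
                        grid = grid_spec()) {
  stopifnot(inherits(scores, "regfed_scores") || is.data.frame(scores),
            inherits(ts, "regfed_test_set"),
            inherits(grid, "regfed_grid_spec"))
  needed <- unique(unlist(lapply(templates, `[[`, "score_names")))
  miss <- setdiff(needed, names(grid$grids))
  if (length(miss)) stop("no grid for score(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  parts <- lapply(templates, function(tp)
    .template_metrics(scores, ts, tp$score_names, grid$grids))
  all_rows <- do.call(rbind, parts)
  n_eval <- nrow(all_rows)
  feas <- all_rows[all_rows$test_recall >= grid$min_test_recall, , drop = FALSE]
  if (nrow(feas) == 0L)
    warning("no configuration satisfies test_recall >= ", grid$min_test_recall)
  key <- .ranking_sort_key(feas)
  hpr <- ifelse(is.na(feas$high_priority_recall), -Inf,
                feas$high_priority_recall)
  feas <- feas[order(feas$positive_rate, -hpr,
                     -feas$test_recall, feas$n_clauses, key), , drop = FALSE]
  rownames(feas) <- NULL
  structure(list(ranking = feas, n_evaluated = n_eval,
                 min_test_recall = grid$min_test_recall,
                 feasible = nrow(feas) > 0L),
            class = "regfed_grid_search")
}

.ranking_sort_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$score_1, sprintf("%010.6f", df$thr_1),
        ifelse(is.na(df$score_2), "", df$score_2),
        ifelse(is.na(df$thr_2), "", sprintf("%010.6f", df$thr_2)))
}

#' @export
print.regfed_grid_search <- function(x, ...) {
  cat(sprintf("<regfed_grid_search> %d grid points evaluated, %d feasible (test_recall >= %g)\n",
              x$n_evaluated, nrow(x$ranking), x$min_test_recall))
  if (nrow(x$ranking)) {
    cat("  best:", ranking_config(x)$label,
        sprintf("(PR %.4f, TR %.3f, HPR %.3f)\n", x$ranking$positive_rate[1L],
                x$ranking$test_recall[1L], x$ranking$high_priority_recall[1L]))
  }
  invisible(x)
}

#' Rebuild a threshold configuration from a grid-search ranking row
#'
#' @param gs a `regfed_grid_search` (or its `ranking` data frame).
#' @param i row index (default 1: the top-ranked configuration).
#' @return a [threshold_config()].
#' @export
ranking_config <- function(gs, i = 1L) {
  df <- if (inherits(gs, "regfed_grid_search")) gs$ranking else gs
  stopifnot(nrow(df) >= i)
  cl <- stats::setNames(df$thr_1[i], df$score_1[i])
  if (!is.na(df$score_2[i]))
    cl <- c(cl, stats::setNames(df$thr_2[i], df$score_2[i]))
  threshold_config(cl)
}

#' Pairwise error correlation between methods
#'
#' For each method, builds the binary error indicator over the test set's
#' relevant documents (1 = missed) and returns the pairwise Pearson (phi)
#' correlation matrix. A method with a zero-variance error vector (all
#' caught or all missed) yields `NA` off-diagonals, flagged in the
#' `"undefined"` attribute.
#'
#' @param per_method_labels named list (>= 2 entries) of
#'   `regfed_classification` objects or label data frames.
#' @param ts a [test_set()].
#' @return correlation matrix with unit diagonal.
#' @export
error_correlation <- function(per_method_labels, ts) {
  stopifnot(is.list(per_method_labels), length(per_method_labels) >= 2L,
            inherits(ts, "regfed_test_set"))
  errs <- vapply(per_method_labels, function(lb) {
    pos <- .positive_ids(lb)
    as.numeric(!(ts$relevant_ids %in% pos))
  }, numeric(length(ts$relevant_ids)))
  colnames(errs) <- names(per_method_labels) %||%
    paste0("method", seq_along(per_method_labels))
  sds <- apply(errs, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(errs))
  diag(cm) <- 1
  attr(cm, "undefined") <- colnames(errs)[sds == 0]
  cm
}

#' Threshold position in corpus score-distribution units
#'
#' Summarizes where a threshold sits relative to the corpus distribution of
#' a score: mean, standard deviation (population by default) and the
#' z-position `(threshold - mean) / sd`. Degenerate distributions (zero
#' spread) are flagged undefined.
#'
#' @param scores a `regfed_scores` table.
#' @param score_name one of [score_names()].
#' @param threshold threshold value.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return list: `score_name`, `mean`, `sd`, `z`, `undefined`.
#' @export
sigma_position <- function(scores, score_name, threshold,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- scores[[score_name]]
  if (is.null(x)) stop("unknown score: ", score_name, call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 documents", call. = FALSE)
  mu <- mean(x)
  s <- if (sd_type == "population") sqrt(mean((x - mu)^2)) else stats::sd(x)
  if (s == 0)
    return(list(score_name = score_name, mean = mu, sd = 0, z = NA_real_,
                undefined = TRUE))
  list(score_name = score_name, mean = mu, sd = s, z = (threshold - mu) / s,
       undefined = FALSE)
}
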