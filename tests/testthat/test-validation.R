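mk_scores <- function(df) {
  df$doc_id <- df$doc_id %||% sprintf("s%03d", seq_len(nrow(df)))
  class(df) <- c("regfed_scores", "data.frame")
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("boundary membership is an inclusive window on one score", {
  sc <- mk_scores(data.frame(doc_id = c("a", "b", "c", "d"),
                             ai_keyword_combined_score = c(0.32, 0.33, 0.34, 0.50)))
  reg <- boundary_region("ai_keyword_combined_score", 0.33, "narrow")
  expect_setequal(boundary_members(sc, reg), c("a", "b", "c"))
  far <- boundary_region("ai_keyword_combined_score", 0.9, "narrow")
  expect_length(boundary_members(sc, far), 0L)
})

test_that("boundary membership matches a per-document predicate loop", {
  fx <- scored_fixture()
  set.seed(12)
  for (trial in 1:25) {
    sname <- sample(c("avg_ref_score", "ai_keyword_combined_score"), 1)
    center <- runif(1, 0.1, 0.5)
    mode <- sample(c("narrow", "wide"), 1)
    reg <- boundary_region(sname, center, mode, scores = fx$scores)
    got <- boundary_members(fx$scores, reg)
    want <- character(0)
    for (i in seq_len(nrow(fx$scores)))
      if (abs(fx$scores[[sname]][i] - center) <= reg$half_width + reg$tol)
        want <- c(want, fx$scores$doc_id[i])
    expect_setequal(got, want)
  }
})

test_that("wide regions contain their narrow counterparts when 0.5*sd >= 0.01", {
  fx <- scored_fixture()
  for (sname in c("avg_ref_score", "ai_keyword_combined_score")) {
    wide <- boundary_region(sname, 0.3, "wide", scores = fx$scores)
    if (wide$half_width >= 0.01) {
      narrow <- boundary_region(sname, 0.3, "narrow")
      expect_true(all(boundary_members(fx$scores, narrow) %in%
                        boundary_members(fx$scores, wide)))
    }
  }
})

test_that("boundary deltas follow the percentage-point convention", {
  # region built so the single method catches 7/16 relevant (43.8%) and the
  # ensemble 15/16 (93.8%): delta must be +50.0 pp
  n <- 16
  kw <- rep(0.33, n)                 # all inside the narrow window
  kw[8:16] <- 0.325                  # below threshold: missed by keyword
  avg <- rep(0, n)
  avg[8:15] <- 0.60                  # reference similarity rescues 8 of the 9
  sc <- mk_scores(data.frame(ai_keyword_combined_score = kw,
                             avg_ref_score = avg,
                             max_ref_score = pmax(avg, 0),
                             ideal_score = 0))
  ts <- test_set(sc$doc_id)
  cfg <- threshold_config(c(ai_keyword_combined_score = 0.33,
                            avg_ref_score = 0.49))
  ba <- boundary_analysis(sc, ts, cfg, modes = "narrow")
  row <- ba[ba$boundary_score == "ai_keyword_combined_score" &
              ba$method == "ai_keyword_combined_score", ]
  expect_equal(row$method_recall, 7 / 16)
  expect_equal(row$ensemble_recall, 15 / 16)
  expect_equal(row$recall_delta_pp, 100 * (15 / 16 - 7 / 16))
  expect_equal(round(row$recall_delta_pp, 1), 50.0)
})

test_that("a degenerate one-clause ensemble has all-zero deltas", {
  fx <- scored_fixture()
  cfg <- threshold_config(c(avg_ref_score = 0.33))
  ba <- boundary_analysis(fx$scores, fx$ts, cfg)
  defined <- ba[ba$recall_defined, ]
  expect_true(all(defined$recall_delta_pp == 0))
  expect_true(all(ba$positive_rate_delta_pp == 0 |
                    is.na(ba$positive_rate_delta_pp)))
})

test_that("within any region the ensemble recall dominates each method", {
  fx <- scored_fixture()
  cfg <- threshold_config(c(ai_keyword_combined_score = 0.28,
                            avg_ref_score = 0.33))
  ba <- boundary_analysis(fx$scores, fx$ts, cfg)
  defined <- ba[ba$recall_defined, ]
  expect_true(all(defined$ensemble_recall >= defined$method_recall - 1e-12))
  expect_true(all(ba$ensemble_positive_rate >= ba$method_positive_rate - 1e-12))
})

test_that("regions without test-labeled documents are flagged undefined", {
  sc <- mk_scores(data.frame(ai_keyword_combined_score = c(0.33, 0.331),
                             avg_ref_score = 0, max_ref_score = 0,
                             ideal_score = 0))
  ts <- test_set("absent-id-not-in-region")
  sc2 <- rbind(sc, data.frame(doc_id = "absent-id-not-in-region",
                              ai_keyword_combined_score = 0.9,
                              avg_ref_score = 0.9, max_ref_score = 0.9,
                              ideal_score = 0.9))
  class(sc2) <- class(sc)
  cfg <- threshold_config(c(ai_keyword_combined_score = 0.33))
  ba <- boundary_analysis(sc2, ts, cfg, modes = "narrow")
  expect_false(ba$recall_defined[1])
  expect_true(is.na(ba$method_recall[1]))
})

test_that("per-agency positive rates match a counting oracle", {
  docs <- corpus(data.frame(
    doc_id = sprintf("d%04d", 1:2000),
    agency = rep(c("FDA", "EMA"), each = 1000),
    text = "t", stringsAsFactors = FALSE))
  pos <- c(sprintf("d%04d", 1:28), sprintf("d%04d", 1001:1016))
  lab <- data.frame(doc_id = docs$doc_id, label = docs$doc_id %in% pos)
  rep <- per_agency_positive_rates(lab, docs)
  expect_equal(rep$rates$positive_rate[rep$rates$agency == "FDA"], 0.028)
  expect_equal(rep$rates$positive_rate[rep$rates$agency == "EMA"], 0.016)
  expect_equal(rep$max_gap, 0.012)
  expect_equal(rep$ratios$ratio[1], 0.028 / 0.016)
})

test_that("equal rates give zero gap; a single agency is flagged undefined", {
  docs <- corpus(data.frame(doc_id = c("a", "b", "c", "d"),
                            agency = c("FDA", "FDA", "EMA", "EMA"),
                            text = "t", stringsAsFactors = FALSE))
  lab <- data.frame(doc_id = docs$doc_id, label = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(per_agency_positive_rates(lab, docs)$max_gap, 0)
  solo <- corpus(data.frame(doc_id = c("a", "b"), agency = "FDA", text = "t",
                            stringsAsFactors = FALSE))
  rep1 <- per_agency_positive_rates(
    data.frame(doc_id = c("a", "b"), label = c(TRUE, FALSE)), solo)
  expect_false(rep1$gap_defined)
  expect_true(is.na(rep1$max_gap))
})

test_that("random agency/label tables match the brute-force rate loop", {
  set.seed(31)
  for (trial in 1:25) {
    n <- 50
    ags <- sample(c("FDA", "EMA", "WHO"), n, replace = TRUE)
    docs <- corpus(data.frame(doc_id = sprintf("x%03d", 1:n), agency = ags,
                              text = "t", stringsAsFactors = FALSE))
    lab <- data.frame(doc_id = docs$doc_id, label = runif(n) < 0.3)
    rep <- per_agency_positive_rates(lab, docs)
    for (ag in unique(ags)) {
      want <- mean(lab$label[ags == ag])
      expect_equal(rep$rates$positive_rate[rep$rates$agency == ag], want)
    }
  }
})

test_that("reference diversification grows the set and rejects duplicates", {
  refs <- reference_set(generate_reference_docs(n = 27, seed = 7),
                        backend = hash_backend(dim = 256))
  extra <- generate_reference_docs(n = 8, seed = 8, prefix = "ema",
                                   style_shift = 0.5, agency = "EMA")
  bigger <- diversify_references(refs, extra)
  expect_identical(nrow(bigger$real_docs), 35L)
  expect_identical(attr(bigger, "added_ids"), extra$doc_id)
  expect_error(diversify_references(bigger, extra), "duplicate")
})

test_that("adding a reference with identical text leaves max_ref_score unchanged", {
  refs <- reference_set(generate_reference_docs(n = 5, seed = 7),
                        backend = hash_backend(dim = 256))
  clone <- refs$real_docs[1, ]
  clone$doc_id <- "clone-001"
  clone <- corpus(as.data.frame(clone), provenance = "clone")
  bigger <- diversify_references(refs, clone)
  probe <- make_docs(5, text = "machine learning oversight of clinical trials")
  s1 <- score_corpus(probe, refs)
  s2 <- score_corpus(probe, bigger)
  expect_equal(s2$max_ref_score, s1$max_ref_score, tolerance = 1e-12)
})
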