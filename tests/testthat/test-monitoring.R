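mk_snapshot <- function(urls, lm = "2025-01-01", digest = NA_character_,
                        source = "fda") {
  snapshot(data.frame(url = urls, last_modified = lm, digest = digest,
                      stringsAsFactors = FALSE), source = source)
}

test_that("identical snapshots diff to three empty sets", {
  s <- mk_snapshot(c("u1", "u2"))
  d <- diff_snapshots(s, s)
  expect_length(d$new_urls, 0L)
  expect_length(d$updated_urls, 0L)
  expect_length(d$removed_urls, 0L)
})

test_that("one added, one touched, one removed are classified 1/1/1", {
  old <- mk_snapshot(c("keep", "touch", "drop"))
  new <- snapshot(data.frame(
    url = c("keep", "touch", "add"),
    last_modified = c("2025-01-01", "2025-02-01", "2025-02-01"),
    stringsAsFactors = FALSE), source = "fda")
  d <- diff_snapshots(old, new)
  expect_identical(d$new_urls, "add")
  expect_identical(d$updated_urls, "touch")
  expect_identical(d$removed_urls, "drop")
})

test_that("digest changes mark updates even with unchanged timestamps", {
  old <- mk_snapshot("u1", digest = "aaa")
  new <- mk_snapshot("u1", digest = "bbb")
  expect_identical(diff_snapshots(old, new)$updated_urls, "u1")
})

test_that("cross-source diffs are fatal and duplicate urls rejected", {
  expect_error(diff_snapshots(mk_snapshot("u", source = "fda"),
                              mk_snapshot("u", source = "ema")),
               "different sources")
  expect_error(mk_snapshot(c("u", "u")), "duplicate")
})

test_that("random snapshot diffs equal a set-algebra oracle", {
  set.seed(8)
  for (trial in 1:10) {
    pool <- sprintf("https://x/%04d", 1:500)
    ou <- sample(pool, 400)
    nu <- sample(pool, 400)
    olm <- sample(c("t1", "t2"), 400, replace = TRUE)
    nlm <- sample(c("t1", "t2"), 400, replace = TRUE)
    old <- snapshot(data.frame(url = ou, last_modified = olm), source = "s")
    new <- snapshot(data.frame(url = nu, last_modified = nlm), source = "s")
    d <- diff_snapshots(old, new)
    expect_setequal(d$new_urls, setdiff(nu, ou))
    expect_setequal(d$removed_urls, setdiff(ou, nu))
    common <- intersect(ou, nu)
    want_upd <- common[olm[match(common, ou)] != nlm[match(common, nu)]]
    expect_setequal(d$updated_urls, want_upd)
    expect_length(intersect(d$new_urls, d$updated_urls), 0L)
  }
})

test_that("snapshots persist and reload", {
  s <- mk_snapshot(c("u1", "u2"), digest = c("d1", NA))
  f <- withr::local_tempfile()
  write_snapshot(s, f)
  back <- read_snapshot(f)
  expect_identical(back$entries, s$entries)
  expect_identical(back$source, s$source)
})

.pipeline_fixture <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    fx <- scored_fixture()
    cfg <- threshold_config(c(ai_keyword_combined_score = 0.28,
                              avg_ref_score = 0.33))
    memo <<- classification_pipeline(fx$refs, cfg)
    memo
  }
})

test_that("an empty batch leaves state unchanged with an undefined rate", {
  pl <- .pipeline_fixture()
  st <- monitor_state()
  out <- incremental_update(st, make_docs(0), pl)
  expect_identical(out$state, st)
  expect_false(out$report$rate_defined)
  expect_true(is.na(out$report$positive_rate))
})

test_that("incremental batch classification equals a standalone pipeline run", {
  fx <- scored_fixture()
  pl <- .pipeline_fixture()
  batch <- fx$lc$corpus[1:100, ]
  class(batch) <- class(fx$lc$corpus)
  out <- incremental_update(monitor_state(), batch, pl)
  standalone <- classify_corpus(score_corpus(batch, pl$refs), pl$config)
  got <- monitor_labels(out$state)
  expect_identical(got$label[match(standalone$labels$doc_id, got$doc_id)],
                   standalone$labels$label)
  expect_identical(out$report$n_new, 100L)
  expect_identical(out$report$n_positive, standalone$n_positive)
})

test_that("re-presenting an unchanged batch is a ledger no-op", {
  fx <- scored_fixture()
  pl <- .pipeline_fixture()
  batch <- fx$lc$corpus[1:20, ]
  class(batch) <- class(fx$lc$corpus)
  once <- incremental_update(monitor_state(), batch, pl)
  twice <- incremental_update(once$state, batch, pl)
  expect_identical(nrow(twice$state$ledger), nrow(once$state$ledger))
  expect_false(twice$report$rate_defined)
})

test_that("updated documents are re-scored and both labels stay in the ledger", {
  fx <- scored_fixture()
  pl <- .pipeline_fixture()
  batch <- fx$lc$corpus[1:5, ]
  class(batch) <- class(fx$lc$corpus)
  st <- incremental_update(monitor_state(), batch, pl)$state
  batch2 <- batch
  batch2$text[1] <- paste(batch2$text[1],
                          "machine learning artificial intelligence guidance")
  class(batch2) <- class(batch)
  out <- incremental_update(st, batch2, pl)
  expect_identical(out$report$n_new, 1L)
  led <- out$state$ledger
  expect_identical(sum(led$doc_id == batch$doc_id[1]), 2L)
  expect_setequal(led$event[led$doc_id == batch$doc_id[1]], c("new", "updated"))
})

test_that("ledger size never decreases across a batch sequence", {
  fx <- scored_fixture()
  pl <- .pipeline_fixture()
  st <- monitor_state()
  sizes <- integer(0)
  for (k in 1:3) {
    batch <- fx$lc$corpus[((k - 1) * 30 + 1):(k * 30), ]
    class(batch) <- class(fx$lc$corpus)
    st <- incremental_update(st, batch, pl)$state
    sizes <- c(sizes, nrow(st$ledger))
  }
  expect_true(all(diff(sizes) >= 0))
  expect_identical(nrow(st$batches), 3L)
})

test_that("an invalid pipeline fails before any state mutation", {
  st <- monitor_state()
  expect_error(incremental_update(st, make_docs(2), list(refs = NULL)),
               "pipeline component")
  expect_identical(nrow(st$ledger), 0L)
})

test_that("monitor state persists atomically and round-trips", {
  fx <- scored_fixture()
  pl <- .pipeline_fixture()
  batch <- fx$lc$corpus[1:10, ]
  class(batch) <- class(fx$lc$corpus)
  st <- incremental_update(monitor_state(), batch, pl)$state
  dir <- withr::local_tempdir()
  write_monitor_state(st, dir)
  back <- read_monitor_state(dir)
  expect_identical(back$known$doc_id, st$known$doc_id)
  expect_identical(back$known$label, st$known$label)
  expect_identical(back$ledger$event, st$ledger$event)
  expect_equal(back$batches$positive_rate, st$batches$positive_rate)
  expect_length(list.files(dir, pattern = "tmp"), 0L)
})

test_that("generated snapshot pairs have the promised diff", {
  lc <- generate_corpus(generator_params(n_docs = 200, seed = 5))
  pair <- generate_snapshot_pair(lc, n_new = 12, n_updated = 7, seed = 2)
  d <- diff_snapshots(pair$old, pair$new)
  expect_setequal(d$new_urls, pair$expected$new_urls)
  expect_setequal(d$updated_urls, pair$expected$updated_urls)
  expect_setequal(d$removed_urls, pair$expected$removed_urls)
  same <- generate_snapshot_pair(lc, n_new = 0, n_updated = 0, seed = 2)
  d0 <- diff_snapshots(same$old, same$new)
  expect_length(c(d0$new_urls, d0$updated_urls, d0$removed_urls), 0L)
})
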