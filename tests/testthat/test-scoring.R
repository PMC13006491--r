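test_that("embedding is deterministic, unit-norm, and flags empty text", {
  bk <- hash_backend()
  v1 <- embed("machine learning in drug regulation", bk)
  v2 <- embed("machine learning in drug regulation", bk)
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-9)
  z <- embed("", bk)
  expect_true(attr(z, "empty"))
  expect_identical(sum(abs(z)), 0)
  # normalization-insensitive: case and punctuation do not matter
  expect_identical(as.numeric(embed("AI-based Tools!", bk)),
                   as.numeric(embed("ai based tools", bk)))
})

test_that("cosine similarity obeys identity, orthogonality, symmetry and an arithmetic oracle", {
  v <- embed("regulatory guidance on neural networks")
  expect_equal(cosine_similarity(v, v), 1, tolerance = 1e-12)
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_identical(cosine_similarity(e1, e2), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(64); b <- rnorm(64)
    oracle <- sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))
    expect_equal(cosine_similarity(a, b), oracle, tolerance = 1e-12)
    expect_identical(cosine_similarity(a, b), cosine_similarity(b, a))
  }
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("synthetic ideal document concatenates all taxonomy terms once, deterministically", {
  tax <- taxonomy("a1", "l1", "b1")
  expect_identical(build_synthetic_reference(tax)$text, "a1 l1 b1")
  tax2 <- taxonomy(paste0("a", 1:5), paste0("l", 1:4), paste0("b", 1:3))
  doc <- build_synthetic_reference(tax2)
  expect_identical(doc$text, build_synthetic_reference(tax2)$text)
  toks <- strsplit(doc$text, " ")[[1]]
  expect_identical(sort(toks), sort(c(paste0("a", 1:5), paste0("l", 1:4),
                                      paste0("b", 1:3))))
  expect_identical(anyDuplicated(toks), 0L)
})

test_that("reference scores equal a brute-force per-reference loop", {
  fx <- scored_fixture()
  refs <- fx$refs
  doc <- fx$lc$corpus$text[5]
  v <- embed(doc, refs$backend)
  rs <- reference_scores(v, refs)
  sims <- vapply(seq_len(nrow(refs$real_docs)), function(i)
    cosine_similarity(v, refs$real_emb[i, ]), numeric(1))
  expect_equal(rs$avg_ref_score, mean(sims), tolerance = 1e-12)
  expect_equal(rs$max_ref_score, max(sims), tolerance = 1e-12)
  expect_equal(rs$ideal_score, cosine_similarity(v, refs$ideal_emb),
               tolerance = 1e-12)
})

test_that("a reference identical to the document yields avg = max = 1", {
  txt <- "machine learning guidance for clinical development"
  refs <- reference_set(make_docs(1, text = txt, prefix = "ref"),
                        tax = tiny_taxonomy())
  rs <- reference_scores(embed(txt, refs$backend), refs)
  expect_equal(rs$avg_ref_score, 1, tolerance = 1e-9)
  expect_equal(rs$max_ref_score, 1, tolerance = 1e-9)
})

test_that("keyword domain score follows the saturating weighted-coverage formula", {
  terms <- c("alpha", "beta", "gamma", "delta")
  expect_identical(keyword_domain_score("no matching words here", terms), 0)
  sat <- paste(rep(terms, 3), collapse = " ")
  expect_equal(keyword_domain_score(sat, terms), 1)
  # counts {0, 1, 3, 5} at cap 3 -> (0 + 1/3 + 1 + 1)/4
  text <- paste(c(rep("beta", 1), rep("gamma", 3), rep("delta", 5)),
                collapse = " ")
  expect_equal(keyword_domain_score(text, terms, cap = 3), (0 + 1/3 + 1 + 1) / 4)
  # verify against a counting oracle that avoids the package matcher
  toks <- strsplit(text, " ")[[1]]
  oracle <- mean(vapply(terms, function(t) min(sum(toks == t), 3) / 3,
                        numeric(1)))
  expect_equal(keyword_domain_score(text, terms, cap = 3), oracle)
})

test_that("multi-token phrases match contiguously and without overlap", {
  expect_equal(keyword_domain_score("machine learning is here",
                                    c("machine learning"), cap = 1), 1)
  expect_identical(keyword_domain_score("machine deep learning",
                                        c("machine learning"), cap = 1), 0)
  # self-overlapping phrase: "a a" occurs once (non-overlapping) in "a a a"
  expect_equal(keyword_domain_score("a a a", c("a a"), cap = 3), (1/3))
})

test_that("keyword score is monotone non-decreasing in term counts", {
  terms <- c("alpha", "beta gamma")
  base <- "alpha filler beta gamma filler"
  s0 <- keyword_domain_score(base, terms)
  s1 <- keyword_domain_score(paste(base, "alpha"), terms)
  s2 <- keyword_domain_score(paste(base, "alpha beta gamma"), terms)
  expect_true(s0 <= s1 && s1 <= s2)
})

test_that("combined keyword score is the weighted mean of domain scores", {
  tax <- tiny_taxonomy()
  # all three domains saturated -> 1 under any weights
  sat <- paste(rep(c("a1", "machine learning", "l1", "l2", "b1"), 3),
               collapse = " ")
  expect_equal(combined_keyword_score(sat, tax, c(0.2, 0.5, 0.3)), 1)
  expect_error(combined_keyword_score(sat, tax, c(0, 0, 0)), "zero")
  set.seed(4)
  for (i in 1:10) {
    txt <- paste(sample(c("a1", "l1", "l2", "b1", "x", "y"), 30, TRUE),
                 collapse = " ")
    w <- runif(3)
    parts <- c(keyword_domain_score(txt, tax$ai_terms),
               keyword_domain_score(txt, tax$legal_regulatory_terms),
               keyword_domain_score(txt, tax$biomedical_terms))
    expect_equal(combined_keyword_score(txt, tax, w),
                 sum(w * parts) / sum(w), tolerance = 1e-12)
  }
})

test_that("score_corpus equals composing the stage operations document by document", {
  fx <- scored_fixture()
  sub <- fx$lc$corpus[1:20, ]
  class(sub) <- class(fx$lc$corpus)
  tab <- score_corpus(sub, fx$refs)
  for (i in seq_len(nrow(sub))) {
    v <- embed(sub$text[i], fx$refs$backend)
    rs <- reference_scores(v, fx$refs)
    expect_equal(tab$avg_ref_score[i], rs$avg_ref_score, tolerance = 1e-12)
    expect_equal(tab$max_ref_score[i], rs$max_ref_score, tolerance = 1e-12)
    expect_equal(tab$ideal_score[i], rs$ideal_score, tolerance = 1e-12)
    expect_equal(tab$ai_keyword_combined_score[i],
                 combined_keyword_score(sub$text[i], fx$refs$taxonomy),
                 tolerance = 1e-12)
  }
})

test_that("scoring is deterministic and order-independent", {
  fx <- scored_fixture()
  sub <- fx$lc$corpus[1:30, ]
  class(sub) <- class(fx$lc$corpus)
  t1 <- score_corpus(sub, fx$refs)
  perm <- sample(nrow(sub))
  sub2 <- sub[perm, ]
  class(sub2) <- class(sub)
  t2 <- score_corpus(sub2, fx$refs)
  reord <- t2[match(t1$doc_id, t2$doc_id), ]
  rownames(reord) <- NULL
  expect_equal(reord$avg_ref_score, t1$avg_ref_score, tolerance = 1e-12)
  expect_equal(reord$ai_keyword_combined_score, t1$ai_keyword_combined_score,
               tolerance = 1e-12)
})

test_that("avg_ref_score never exceeds max_ref_score and adding a reference never lowers max", {
  fx <- scored_fixture()
  expect_true(all(fx$scores$avg_ref_score <= fx$scores$max_ref_score + 1e-12))
  extra <- generate_reference_docs(n = 1, seed = 333, prefix = "extra")
  bigger <- diversify_references(fx$refs, extra)
  sub <- fx$lc$corpus[1:40, ]
  class(sub) <- class(fx$lc$corpus)
  before <- score_corpus(sub, fx$refs)$max_ref_score
  after <- score_corpus(sub, bigger)$max_ref_score
  expect_true(all(after >= before - 1e-12))
})

test_that("score tables persist and reload", {
  fx <- scored_fixture()
  sub <- fx$scores[1:5, ]
  class(sub) <- class(fx$scores)
  f <- withr::local_tempfile()
  write_scores(sub, f)
  back <- read_scores(f)
  expect_equal(back$avg_ref_score, sub$avg_ref_score, tolerance = 1e-12)
  expect_identical(back$doc_id, sub$doc_id)
})

test_that("taxonomy file format round-trips including weights", {
  tax <- taxonomy(c(alpha = 2, "machine learning" = 1),
                  c(l1 = 1), c(b1 = 0.5))
  f <- withr::local_tempfile()
  write_taxonomy(tax, f)
  expect_identical(read_taxonomy(f), tax)
})
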