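toy_psd_index <- function() build_index(tiny_corpus(psd_toy_texts), stopwords = character())

test_that("PSD term weights reproduce the hand-computed toy values", {
  expect_equal(psd_term_weight(1, 1, 3, 5), log(506 / 2503), tolerance = 1e-12)
  expect_equal(psd_term_weight(0, 1, 3, 5), log(500 / 2503), tolerance = 1e-12)
  expect_true(is.na(psd_term_weight(0, 0, 3, 5)))
  # and through the index on the same fixed instance
  idx <- toy_psd_index()
  expect_equal(psd_score("tgf", "D1", idx), log(506 / 2503), tolerance = 1e-12)
  expect_equal(psd_score("zeta", "D1", idx), log(500 / 2503), tolerance = 1e-12)
  expect_identical(psd_score(character(), "D1", idx), 0)
})

test_that("the presence indicator strictly rewards tf = 1 over tf = 0 on a grid", {
  grid <- expand.grid(cf = c(1, 2, 5, 50), dl = c(1, 10, 100), C = c(100, 1000, 1e6))
  for (i in seq_len(nrow(grid))) {
    w1 <- psd_term_weight(1, grid$cf[[i]], grid$dl[[i]], grid$C[[i]])
    w0 <- psd_term_weight(0, grid$cf[[i]], grid$dl[[i]], grid$C[[i]])
    expect_gt(w1, w0)
  }
})

test_that("psd_score equals the from-scratch oracle on randomized toy corpora", {
  vocab <- c("tgf", "beta", "signal", "pathway", "gene", "cell", "tumor", "assay")
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:20, 1L)
    texts <- stats::setNames(
      vapply(seq_len(n), function(i)
        paste(sample(vocab, sample(2:15, 1L), replace = TRUE), collapse = " "), ""),
      sprintf("D%02d", seq_len(n)))
    idx <- build_index(tiny_corpus(texts), stopwords = character())
    toks <- oracle_tokens(texts)
    q <- sample(c(vocab, "oovword"), sample(1:5, 1L), replace = TRUE)
    d <- sample(names(texts), 1L)
    expect_equal(psd_score(q, d, idx), oracle_psd_score(q, d, toks), tolerance = 1e-9)
  }
})

test_that("adding a query-token occurrence strictly increases a document's PSD score", {
  texts <- c(D1 = "tgf beta gene", D2 = "cell assay tumor")
  texts2 <- c(D1 = "tgf tgf beta gene", D2 = "cell assay tumor")
  q <- c("tgf", "beta")
  s1 <- psd_score(q, "D1", build_index(tiny_corpus(texts), stopwords = character()))
  s2 <- psd_score(q, "D1", build_index(tiny_corpus(texts2), stopwords = character()))
  expect_gt(s2, s1)
})

test_that("PSD re-ranking is a permutation, deterministic, and favors matching docs", {
  texts <- c(D1 = "tgf beta signaling observed", D2 = "unrelated assay material",
             D3 = "tgf mentioned once")
  idx <- build_index(tiny_corpus(texts))
  cand <- ranked_list("T1", names(texts), c(3, 2, 1))
  out <- rerank_psd_allwords("tgf beta signaling", cand, idx)
  expect_setequal(out$doc_id, cand$doc_id)
  expect_identical(out$doc_id[[1L]], "D1")
  expect_gt(match("D2", out$doc_id), match("D3", out$doc_id))
  # permutation invariance of the candidate input order
  shuffled <- ranked_list("T1", c("D2", "D3", "D1"), c(9, 5, 1))
  expect_identical(rerank_psd_allwords("tgf beta signaling", shuffled, idx)$doc_id,
                   out$doc_id)
})

test_that("PSD-keywords reduces to PSD-allwords when the recognizer returns the content words", {
  texts <- c(D1 = "tgf beta pathway", D2 = "assay of cells", D3 = "beta only")
  idx <- build_index(tiny_corpus(texts))
  cand <- ranked_list("T1", names(texts), c(3, 2, 1))
  question <- "tgf beta pathway"
  all_words <- rerank_psd_allwords(question, cand, idx)
  kw <- rerank_psd_keywords(question, cand, idx,
                            recognizer = function(q) c("tgf", "beta", "pathway"))
  expect_identical(kw$doc_id, all_words$doc_id)
  expect_equal(kw$score, all_words$score, tolerance = 1e-12)
  # duplicate recognized concepts count once
  dup <- rerank_psd_keywords(question, cand, idx,
                             recognizer = function(q) c("tgf", "tgf", "beta", "pathway"))
  expect_equal(dup$score, all_words$score, tolerance = 1e-12)
  # empty recognition degenerates to doc_id order with zero scores
  none <- rerank_psd_keywords(question, cand, idx, recognizer = function(q) character())
  expect_identical(none$doc_id, sort(cand$doc_id))
  expect_identical(unique(none$score), 0)
})

test_that("the dictionary recognizer extracts deduplicated in-dictionary phrases", {
  rec <- dictionary_recognizer()
  got <- rec("find data related to TGF-beta signaling pathway across all databases")
  expect_setequal(got, c("TGF-beta", "signaling pathway"))
})

test_that("SQEM reduces to PSD-allwords when the surrogate is the question itself", {
  texts <- c(D1 = "tgf beta pathway", D2 = "assay of cells")
  idx <- build_index(tiny_corpus(texts))
  cand <- ranked_list("T1", names(texts), c(2, 1))
  question <- "tgf beta pathway"
  provider <- function(topic_id, question_in = NULL) question
  out <- rerank_sqem(question, cand, idx, provider, topic_id = "T1")
  ref <- rerank_psd_allwords(question, cand, idx)
  expect_identical(out$doc_id, ref$doc_id)
  expect_equal(out$score, ref$score, tolerance = 1e-12)
  # k = 1 vs k = 10 with a single fixture document are identical
  out1 <- rerank_sqem(question, cand, idx, provider, topic_id = "T1", k = 1L)
  expect_identical(out1$doc_id, out$doc_id)
  # provider with nothing to give is an error naming the topic
  expect_error(rerank_sqem(question, cand, idx,
                           function(topic_id, q = NULL) character(), topic_id = "T9"),
               "T9")
})

test_that("surrogates rich in a planted document's vocabulary promote it", {
  texts <- c(planted = "crispr knockout screen replicates",
             sparse = "miscellaneous record of nothing")
  idx <- build_index(tiny_corpus(texts))
  cand <- ranked_list("T1", names(texts), c(1, 2))   # sparse initially first
  expect_identical(cand$doc_id[[1L]], "sparse")
  provider <- function(topic_id, q = NULL)
    c("crispr knockout screens", "crispr screen replicates in cells")
  out <- rerank_sqem("irrelevant question", cand, idx, provider, topic_id = "T1")
  expect_identical(out$doc_id[[1L]], "planted")
})

test_that("fixture surrogate providers read per-topic paragraph files", {
  dir <- withr::local_tempdir()
  writeLines(c("first surrogate doc", "", "second surrogate doc"),
             file.path(dir, "T1.txt"))
  provider <- fixture_surrogate_provider(dir)
  expect_identical(provider("T1"), c("first surrogate doc", "second surrogate doc"))
  expect_identical(provider("T2"), character())
})

test_that("reciprocal-rank fusion reproduces hand-computed scores", {
  A <- ranked_list("T1", c("d1", "d2", "d3"), c(9, 8, 7))
  B <- ranked_list("T1", c("d2", "d3", "d1"), c(6, 5, 4))
  out <- ensemble(list(A, B))
  # d1: rank 1 in A, rank 3 in B -> (1 + 1/3)/2 = 2/3
  expect_equal(out$score[out$doc_id == "d1"], 2 / 3, tolerance = 1e-12)
  # absence contributes 0: d4 at rank 2 in A only
  A2 <- ranked_list("T1", c("d9", "d4"), c(2, 1))
  B2 <- ranked_list("T1", sprintf("x%02d", 1:10), 10:1)
  out2 <- ensemble(list(A2, B2))
  expect_equal(out2$score[out2$doc_id == "d4"], 0.25, tolerance = 1e-12)
})

test_that("ensemble is a fixed point on identical inputs and validates its inputs", {
  A <- ranked_list("T1", c("d1", "d2", "d3"), c(9, 8, 7))
  out <- ensemble(list(A, A))
  expect_identical(out$doc_id, A$doc_id)
  expect_true(all(out$score > 0 & out$score <= 1))
  expect_equal(out$score[[1L]], 1, tolerance = 1e-12)  # rank 1 everywhere
  expect_lt(max(out$score[-1L]), 1)
  expect_error(ensemble(list(A)), "at least 2")
  B <- ranked_list("T2", "d1", 1)
  expect_error(ensemble(list(A, B)), "share one topic")
})
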