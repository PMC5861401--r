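qrels_of <- function(grades, topic = "T1") {
  qrels(data.frame(topic = topic, doc_id = names(grades), grade = unname(grades)))
}

run_of <- function(docs, topic = "T1") {
  ranked_list(topic, docs, seq(length(docs), 1L), sort = FALSE)
}

test_that("P@10 counts grades against a fixed denominator of 10", {
  g <- c(a = 2, b = 1, c = 0, d = 0, e = 2, f = 0, g = 0, h = 0, i = 0, j = 0,
         z1 = 0, z2 = 0)
  q <- qrels_of(g)
  run <- run_of(names(g)[1:10])
  expect_equal(precision_at_10(run, q, TRUE)$mean, 0.3)
  expect_equal(precision_at_10(run, q, FALSE)$mean, 0.2)
  # all top-10 relevant
  q2 <- qrels_of(stats::setNames(rep(2, 10), letters[1:10]))
  expect_equal(precision_at_10(run_of(letters[1:10]), q2, TRUE)$mean, 1)
  expect_equal(precision_at_10(run_of(letters[1:10]), q2, FALSE)$mean, 1)
  # short run: denominator stays 10
  q3 <- qrels_of(c(a = 2, b = 2, c = 1, d = 0))
  expect_equal(precision_at_10(run_of(c("a", "b", "c", "d")), q3, TRUE)$mean, 0.3)
})

test_that("NDCG@10 matches hand-computed values and its boundary cases", {
  # ideal ordering scores exactly 1
  g <- c(a = 2, b = 2, c = 1, d = 0)
  expect_equal(ndcg_at_10(run_of(c("a", "b", "c", "d")), qrels_of(g))$mean, 1)
  # all-zero retrieval scores 0
  expect_equal(ndcg_at_10(run_of(c("d", "e")), qrels_of(c(a = 2, d = 0, e = 0)))$mean, 0)
  # run order [1, 2] against qrels {one 2, one 1}
  q <- qrels_of(c(p = 1, r = 2))
  got <- ndcg_at_10(run_of(c("p", "r")), q)$mean
  want <- (1 / log2(2) + 2 / log2(3)) / (2 / log2(2) + 1 / log2(3))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(want, 4), 0.8597)
})

test_that("promoting a higher-graded document never decreases NDCG@10", {
  set.seed(5)
  for (rep in 1:25) {
    docs <- sprintf("d%02d", 1:12)
    g <- stats::setNames(sample(0:2, 12, replace = TRUE), docs)
    if (all(g == 0)) g[[1L]] <- 2
    q <- qrels_of(g)
    ord <- sample(docs)
    i <- sample(11, 1L)
    before <- ndcg_at_10(run_of(ord), q)$mean
    if (g[[ord[i]]] < g[[ord[i + 1L]]]) {
      ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
      expect_gte(ndcg_at_10(run_of(ord), q)$mean, before)
    }
  }
})

test_that("per-topic invariants hold: metrics in [0,1] and -partial <= +partial", {
  bench <- small_benchmark()
  idx <- build_index(bench$corpus, bench$schema)
  runs <- lapply(seq_len(nrow(bench$questions)), function(i)
    retrieve_cascade(idx, generate_query(bench$questions$topic_id[[i]],
                                         bench$questions$question[[i]],
                                         bench$dictionary)))
  res <- evaluate_run(runs, bench$qrels)
  expect_true(all(res$per_topic >= 0 & res$per_topic <= 1))
  expect_true(all(res$per_topic$p10minus <= res$per_topic$p10plus))
})

test_that("inf_ap reduces to exact AP on fully judged runs", {
  g <- c(a = 2, b = 0, c = 1, d = 0, e = 0)
  q <- qrels_of(g)
  run <- run_of(c("a", "b", "c", "d", "e"))
  # relevant at ranks 1 and 3 of a fully judged run: AP = (1/1 + 2/3)/2
  expect_equal(inf_ap(run, q)$mean, (1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(inf_ap(run, q)$mean, oracle_ap(run$doc_id, as.list(g)), tolerance = 1e-12)
  # empty run scores 0
  empty <- ranked_list("T1", character(), numeric())
  expect_equal(inf_ap(empty, q)$mean, 0)
  # 100 percent sample with explicit metadata equals exact AP to 1e-9
  s100 <- subsample_qrels(q, 1, seed = 3)
  expect_equal(inf_ap(run, s100)$mean, inf_ap(run, q)$mean, tolerance = 1e-9)
})

test_that("inf_ndcg reduces to exact full-list NDCG at 100 percent sampling", {
  set.seed(11)
  docs <- sprintf("d%03d", 1:60)
  g <- stats::setNames(sample(0:2, 60, replace = TRUE, prob = c(.6, .2, .2)), docs)
  q <- qrels_of(g)
  run <- run_of(sample(docs, 45))
  exact <- oracle_ndcg_full(run$doc_id, as.list(g))
  expect_equal(inf_ndcg(run, q)$mean, exact, tolerance = 1e-9)
  s100 <- subsample_qrels(q, 1, seed = 5)
  expect_equal(inf_ndcg(run, s100)$mean, exact, tolerance = 1e-9)
  # zero judged-relevant docs scores 0
  q0 <- qrels_of(stats::setNames(rep(0, 5), letters[1:5]))
  expect_equal(inf_ndcg(run_of(letters[1:5]), q0)$mean, 0)
})

test_that("inferred measures are unbiased under 50 percent subsampling", {
  set.seed(7)
  docs <- sprintf("D%03d", 1:400)
  grade <- ifelse(stats::runif(400) < pmax(0.05, 0.6 - (1:400) / 500),
                  sample(1:2, 400, replace = TRUE), 0)
  q <- qrels(data.frame(topic = "T1", doc_id = docs, grade = grade))
  run <- ranked_list("T1", docs, seq(400, 1), sort = FALSE)
  exact_ap <- inf_ap(run, q)$mean
  exact_ndcg <- inf_ndcg(run, q)$mean
  B <- 200
  aps <- numeric(B); nds <- numeric(B)
  for (b in seq_len(B)) {
    sq <- subsample_qrels(q, 0.5, seed = b)
    aps[[b]] <- inf_ap(run, sq)$mean
    nds[[b]] <- inf_ndcg(run, sq)$mean
  }
  expect_lt(abs(mean(aps) - exact_ap), 2 * stats::sd(aps) / sqrt(B))
  expect_lt(abs(mean(nds) - exact_ndcg), 2 * stats::sd(nds) / sqrt(B))
})

test_that("exact metrics agree with the independent Python reference evaluator", {
  bench <- small_benchmark()
  idx <- build_index(bench$corpus, bench$schema)
  runs <- lapply(seq_len(nrow(bench$questions)), function(i)
    retrieve_cascade(idx, generate_query(bench$questions$topic_id[[i]],
                                         bench$questions$question[[i]],
                                         bench$dictionary)))
  run_path <- withr::local_tempfile(fileext = ".run")
  qrels_path <- withr::local_tempfile(fileext = ".qrels")
  write_run(runs, run_path)
  write_qrels(bench$qrels, qrels_path)
  oracle_script <- system.file("oracle", "eval_oracle.py", package = "datasearch")
  out <- system2("python", c(oracle_script, run_path, qrels_path), stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))
  run_df <- read_run(run_path)
  expect_equal(ndcg_at_10(run_df, bench$qrels)$mean, ref$ndcg10_mean, tolerance = 1e-6)
  expect_equal(precision_at_10(run_df, bench$qrels, TRUE)$mean, ref$p10plus_mean,
               tolerance = 1e-6)
  expect_equal(precision_at_10(run_df, bench$qrels, FALSE)$mean, ref$p10minus_mean,
               tolerance = 1e-6)
  expect_equal(inf_ap(run_df, bench$qrels)$mean, ref$ap_mean, tolerance = 1e-6)
})

test_that("run and qrels files round-trip through their readers", {
  bench <- small_benchmark()
  idx <- build_index(bench$corpus, bench$schema)
  run <- retrieve_cascade(idx, generate_query(bench$questions$topic_id[[1L]],
                                              bench$questions$question[[1L]],
                                              bench$dictionary))
  rp <- withr::local_tempfile(fileext = ".run")
  write_run(run, rp, tag = "boolean")
  back <- read_run(rp)
  expect_identical(back$doc_id, run$doc_id)
  expect_identical(back$rank, run$rank)
  expect_equal(back$score, run$score, tolerance = 1e-6)

  qp <- withr::local_tempfile(fileext = ".qrels")
  write_qrels(bench$qrels, qp)
  q2 <- read_qrels(qp)
  expect_identical(names(q2), names(bench$qrels))
  for (tp in names(q2))
    expect_identical(q2[[tp]]$judgments[order(names(q2[[tp]]$judgments))],
                     bench$qrels[[tp]]$judgments[order(names(bench$qrels[[tp]]$judgments))])
  # sampled dialect round-trips the pool and rates
  sq <- subsample_qrels(bench$qrels, 0.5, seed = 2, strata = "two")
  write_qrels(sq, qp)
  sq2 <- read_qrels(qp)
  for (tp in names(sq2)) {
    expect_identical(sort(names(sq2[[tp]]$pool)), sort(names(sq[[tp]]$pool)))
    expect_equal(sq2[[tp]]$rates[sort(names(sq2[[tp]]$rates))],
                 sq[[tp]]$rates[sort(names(sq[[tp]]$rates))], tolerance = 1e-12)
  }
})

test_that("run topics missing from the qrels are excluded with a warning", {
  q <- qrels_of(c(a = 2, b = 0))
  r1 <- run_of(c("a", "b"), topic = "T1")
  r2 <- run_of(c("a", "b"), topic = "T9")
  expect_warning(res <- precision_at_10(list(r1, r2), q), "T9")
  expect_identical(names(res$per_topic), "T1")
})
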