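# Evaluation against graded qrels: Precision@10 with and without partial
# relevance, NDCG@10 with linear graded gains, and the inferred measures
# infAP and infNDCG that estimate AP / full-list NDCG from a (possibly
# stratified) random sample of the judgment pool. Both inferred estimators
# reduce exactly to their complete-judgment counterparts when every stratum
# is fully sampled.

# Ranked documents per topic from any accepted run representation; empty
# ranked lists keep their topic (and score 0 under every metric).
run_topic_docs <- function(run) {
  if (inherits(run, "ds_ranked_list")) run <- list(run)
  if (is.data.frame(run)) {
    df <- run[order(run$topic, run$rank), ]
    return(split(df$doc_id, df$topic))
  }
  out <- list()
  for (r in run) {
    topic <- attr(r, "topic")
    if (is.null(topic)) {
      if (nrow(r) == 0L) next
      topic <- r$topic[[1L]]
    }
    out[[topic]] <- r$doc_id[order(r$rank)]
  }
  out
}

per_topic_metric <- function(run, q, f) {
  docs_by_topic <- run_topic_docs(run)
  missing <- setdiff(names(docs_by_topic), names(q))
  if (length(missing))
    warning("topic(s) in run but not in qrels, excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
  topics <- intersect(names(docs_by_topic), names(q))
  vals <- vapply(topics, function(topic)
    f(docs_by_topic[[topic]], q[[topic]]), 0)
  list(per_topic = stats::setNames(vals, topics),
       mean = if (length(vals)) mean(vals) else NA_real_)
}

#' Precision at 10
#'
#' Fraction of the top 10 ranks occupied by relevant documents; the
#' denominator is always 10, also for runs shorter than 10 entries. With
#' `include_partial = TRUE` grade 1 counts as relevant (P@10(+partial)),
#' otherwise only grade 2 does (P@10(-partial)). Unjudged documents count as
#' grade 0.
#'
#' @param run A `ds_ranked_list`, list of them, or run `data.frame`.
#' @param q A `ds_qrels`.
#' @param include_partial Count partially relevant documents as relevant?
#' @return A list with `per_topic` (named numeric) and `mean`.
#' @export
precision_at_10 <- function(run, q, include_partial = TRUE) {
  thr <- if (include_partial) 1 else 2
  per_topic_metric(run, q, function(docs, tp) {
    g <- qrels_grades(tp, utils::head(docs, 10L))
    sum(g >= thr) / 10
  })
}

dcg <- function(gains) {
  if (length(gains) == 0L) return(0)
  sum(gains / log2(seq_along(gains) + 1))
}

#' NDCG at 10
#'
#' Discounted cumulative gain over the top 10 results with linear graded
#' gains (relevant = 2, partially relevant = 1, otherwise 0) and discount
#' `1/log2(rank + 1)`, normalized by the ideal DCG@10 computed from the full
#' set of judgments for the topic. Topics without relevant documents score 0.
#'
#' @inheritParams precision_at_10
#' @return A list with `per_topic` and `mean`.
#' @export
ndcg_at_10 <- function(run, q) {
  per_topic_metric(run, q, function(docs, tp) {
    ideal <- sort(tp$judgments, decreasing = TRUE)
    idcg <- dcg(utils::head(ideal[ideal > 0], 10L))
    if (idcg == 0) return(0)
    dcg(qrels_grades(tp, utils::head(docs, 10L))) / idcg
  })
}

# Exact average precision over a fully judged topic: relevant = grade >= 1,
# denominator = total relevant in the qrels.
ap_exact <- function(docs, tp) {
  rel <- qrels_grades(tp, docs) >= 1
  R <- sum(tp$judgments >= 1)
  if (R == 0) return(0)
  k <- which(rel)
  if (length(k) == 0L) return(0)
  sum(cumsum(rel)[k] / k) / R
}

#' Inferred average precision
#'
#' Estimates average precision from a sampled judgment pool: for each sampled
#' relevant document at rank k, the expected precision at k is estimated from
#' the pool composition above k and the within-sample relevance rate of each
#' stratum, and the contributions are inverse-rate weighted against the
#' estimated total number of relevant documents. A small epsilon (1e-5)
#' smooths the within-stratum rate when the stratum is only partially
#' sampled; fully sampled strata use exact counts, so at 100 percent sampling
#' the estimator equals exact AP (relevant = grade >= 1, unretrieved relevant
#' documents counting against the denominator). Qrels without sampling
#' metadata are treated as a 100 percent sample with a warning.
#'
#' @inheritParams precision_at_10
#' @param eps Smoothing constant for partially sampled strata.
#' @return A list with `per_topic` and `mean`.
#' @export
inf_ap <- function(run, q, eps = 1e-5) {
  per_topic_metric(run, q, function(docs, tp) {
    strata <- unique(unname(tp$pool))
    rates <- tp$rates[strata]
    if (all(rates == 1)) return(ap_exact(docs, tp))
    n <- length(docs)
    doc_stratum <- tp$pool[docs]                       # NA if not pooled
    judged <- docs %in% names(tp$judgments)
    grade <- qrels_grades(tp, docs)
    rel <- judged & grade >= 1
    nonrel <- judged & grade == 0
    # cumulative counts above rank k (exclusive), per stratum
    num <- 0
    R_est <- sum(vapply(strata, function(s) {
      in_s <- names(tp$pool)[tp$pool == s]
      sum(tp$judgments[intersect(in_s, names(tp$judgments))] >= 1) / tp$rates[[s]]
    }, 0))
    if (R_est == 0) return(0)
    cum_pool <- lapply(strata, function(s) cumsum(!is.na(doc_stratum) & doc_stratum == s))
    cum_rel  <- lapply(strata, function(s) cumsum(rel & doc_stratum == s & !is.na(doc_stratum)))
    cum_non  <- lapply(strata, function(s) cumsum(nonrel & doc_stratum == s & !is.na(doc_stratum)))
    names(cum_pool) <- names(cum_rel) <- names(cum_non) <- strata
    for (k in which(rel)) {
      est_above <- 0
      for (s in strata) {
        d  <- if (k > 1L) cum_pool[[s]][k - 1L] else 0
        if (d == 0) next
        rs <- if (k > 1L) cum_rel[[s]][k - 1L] else 0
        ns <- if (k > 1L) cum_non[[s]][k - 1L] else 0
        est_above <- est_above +
          (if (rs + ns == d) rs else d * (rs + eps) / (rs + ns + 2 * eps))
      }
      num <- num + (1 / tp$rates[[doc_stratum[[k]]]]) * (1 + est_above) / k
    }
    num / R_est
  })
}

#' Inferred NDCG
#'
#' Estimates full-list NDCG from a sampled judgment pool. The run's DCG is
#' the inverse-sampling-rate weighted (Horvitz-Thompson) sum of the judged
#' gains at their actual ranks: each sampled document contributes
#' `grade / log2(rank + 1)` scaled by `1 / rate` of its stratum, so the
#' estimate is unbiased for the full-judgment DCG under within-stratum
#' uniform sampling. The ideal DCG is built from inverse-rate estimates of
#' the per-grade relevant counts, allocating (possibly fractional) document
#' mass grade 2 first. At 100 percent sampling this equals exact NDCG over
#' the full run.
#'
#' @inheritParams precision_at_10
#' @return A list with `per_topic` and `mean`.
#' @export
inf_ndcg <- function(run, q) {
  per_topic_metric(run, q, function(docs, tp) {
    strata <- unique(unname(tp$pool))
    doc_stratum <- tp$pool[docs]
    judged <- docs %in% names(tp$judgments)
    gains <- numeric(length(docs))
    gains[judged] <- qrels_grades(tp, docs[judged])
    w <- rep(1, length(docs))
    w[judged] <- 1 / tp$rates[doc_stratum[judged]]
    dcg_run <- dcg(gains * w)
    # estimated per-grade counts in the whole pool
    est_count <- function(target) sum(vapply(strata, function(s) {
      in_s <- names(tp$pool)[tp$pool == s]
      sum(tp$judgments[intersect(in_s, names(tp$judgments))] == target) / tp$rates[[s]]
    }, 0))
    m2 <- est_count(2); m1 <- est_count(1)
    idcg <- 0; j <- 1
    while (m2 + m1 > 1e-12) {
      a2 <- min(m2, 1); a1 <- min(m1, 1 - a2)
      idcg <- idcg + (2 * a2 + a1) / log2(j + 1)
      m2 <- m2 - a2; m1 <- m1 - a1; j <- j + 1
    }
    if (idcg == 0) return(0)
    dcg_run / idcg
  })
}

#' Score a run with the full metric set
#'
#' Computes infAP, infNDCG, NDCG@10, P@10(+partial) and P@10(-partial).
#'
#' @inheritParams precision_at_10
#' @param metrics Subset of `c("infap", "infndcg", "ndcg10", "p10plus",
#'   "p10minus")`.
#' @return A list with `mean` (named numeric over metrics) and `per_topic`
#'   (data.frame topics x metrics).
#' @export
evaluate_run <- function(run, q,
                         metrics = c("infap", "infndcg", "ndcg10", "p10plus", "p10minus")) {
  fns <- list(
    infap    = function() inf_ap(run, q),
    infndcg  = function() inf_ndcg(run, q),
    ndcg10   = function() ndcg_at_10(run, q),
    p10plus  = function() precision_at_10(run, q, include_partial = TRUE),
    p10minus = function() precision_at_10(run, q, include_partial = FALSE)
  )
  metrics <- match.arg(metrics, names(fns), several.ok = TRUE)
  res <- lapply(fns[metrics], function(f) f())
  list(
    mean = vapply(res, `[[`, 0, "mean"),
    per_topic = as.data.frame(lapply(res, `[[`, "per_topic"))
  )
}
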