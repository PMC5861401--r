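# Independent oracles and fixture builders shared across tests. The oracles
# recompute scores directly from raw texts / first principles and share no
# code with the indexed implementation they check.

# Build a one-field-per-doc corpus from a named character vector of texts.
tiny_corpus <- function(texts, field = "metadata.description") {
  as_corpus(lapply(names(texts), function(id)
    metadata_record(id, stats::setNames(texts[[id]], field))))
}

# Token lists per doc, straight from the raw texts via the public analyzer.
oracle_tokens <- function(texts, stopwords = character()) {
  lapply(texts, function(tx) analyze(tx, stopwords = stopwords))
}

# From-scratch PSD score: Eq-style computation of tf, cf, |D|, |C| by direct
# counting over token lists, then the log formula summed over query tokens.
oracle_psd_score <- function(qtokens, doc_id, token_lists, delta = 5, mu = 2500) {
  all_tokens <- unlist(token_lists, use.names = FALSE)
  C <- length(all_tokens)
  D <- length(token_lists[[doc_id]])
  s <- 0
  for (t in qtokens) {
    cf <- sum(all_tokens == t)
    tf <- sum(token_lists[[doc_id]] == t)
    if (cf == 0 && tf == 0) next
    s <- s + log(((tf > 0) * (tf + delta) + mu * cf / C) / (D + mu))
  }
  s
}

# From-scratch BM25 with k1 = 1.2, b = 0.75, Lucene-style idf.
oracle_bm25 <- function(terms, doc_id, token_lists, k1 = 1.2, b = 0.75) {
  terms <- unique(terms)
  N <- length(token_lists)
  avgdl <- mean(lengths(token_lists))
  dl <- length(token_lists[[doc_id]])
  s <- 0
  for (t in terms) {
    tf <- sum(token_lists[[doc_id]] == t)
    if (tf == 0) next
    df <- sum(vapply(token_lists, function(x) t %in% x, TRUE))
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / avgdl))
  }
  s
}

# Does `doc` contain the analyzed phrase tokens contiguously? (raw scan)
oracle_has_phrase <- function(phrase_tokens, doc_tokens) {
  L <- length(phrase_tokens)
  if (L == 0L || length(doc_tokens) < L) return(FALSE)
  for (i in seq_len(length(doc_tokens) - L + 1L))
    if (all(doc_tokens[i:(i + L - 1L)] == phrase_tokens)) return(TRUE)
  FALSE
}

# Brute-force cascade: score every document by (concept-match count, BM25,
# doc_id) and sort; equivalent semantics to retrieve_cascade by enumeration.
oracle_cascade <- function(token_lists, concepts, stopwords = character(),
                           min_match = 1L) {
  match_count <- vapply(names(token_lists), function(doc) {
    sum(vapply(concepts, function(con) {
      any(vapply(unique(c(con$surface, con$representations)), function(rep) {
        toks <- analyze(rep, stopwords = stopwords)
        length(toks) > 0L && oracle_has_phrase(toks, token_lists[[doc]])
      }, TRUE))
    }, TRUE))
  }, 0)
  keep <- names(match_count)[match_count >= min_match]
  if (length(keep) == 0L) return(character())
  union_terms <- unique(unlist(lapply(concepts, function(con)
    unlist(lapply(unique(c(con$surface, con$representations)),
                  function(r) analyze(r, stopwords = stopwords))))))
  bm <- vapply(keep, function(d) oracle_bm25(union_terms, d, token_lists), 0)
  keep[order(-match_count[keep], -bm, keep, method = "radix")]
}

# Exact AP / NDCG over a fully judged ranked doc vector (independent of the
# package's evaluators; used to cross-check reductions).
oracle_ap <- function(docs, grades_by_doc) {
  rel <- vapply(docs, function(d) isTRUE(grades_by_doc[[d]] >= 1), TRUE)
  R <- sum(unlist(grades_by_doc) >= 1)
  if (R == 0) return(0)
  k <- which(rel)
  if (length(k) == 0L) return(0)
  sum(cumsum(rel)[k] / k) / R
}

oracle_ndcg_full <- function(docs, grades_by_doc) {
  g <- vapply(docs, function(d) {
    v <- grades_by_doc[[d]]
    if (is.null(v)) 0 else v
  }, 0)
  disc <- function(x) if (length(x)) sum(x / log2(seq_along(x) + 1)) else 0
  ideal <- sort(unlist(grades_by_doc), decreasing = TRUE)
  idcg <- disc(ideal[ideal > 0])
  if (idcg == 0) return(0)
  disc(g) / idcg
}

# Small, fast benchmark used by non-acceptance pipeline tests.
small_benchmark <- function(seed = 99L) {
  generate_benchmark(synthetic_config(
    seed = seed, n_docs = 300L, vocab_size = 600L, n_topics = 3L,
    n_judged_nonrel = 15L, doc_len_mean = 60))
}

# The fixed toy instance behind the hand-computed PSD values: |C| = 5,
# the "tgf"-bearing doc has |D| = 3, cf("tgf") = 1, cf("zeta") = 1.
psd_toy_texts <- c(D1 = "tgf beta pathway", D2 = "zeta omega")

# access to the internal scoping rule
fields_in_scope_for_test <- function(rec, schema) datasearch:::fields_in_scope(rec, schema)

ds_tokenize_for_test <- function(x) datasearch:::ds_tokenize(x)
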