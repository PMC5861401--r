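# Stage-2 re-ranking. The pseudo-sequential-dependence (PSD) model is a
# unigram-only sequential-dependence variant: a Dirichlet-smoothed query
# likelihood in which a presence indicator adds a constant delta to the term
# frequency of any query word that occurs at all, making "does the word occur"
# weigh more than "how often". SQEM re-scores with PSD using a surrogate
# document (concatenated external search snippets) in place of the question;
# the ensemble fuses ranked lists by mean reciprocal rank.

#' PSD hyper-parameters
#'
#' `mu` is the Dirichlet smoothing mass (default 2500); `delta` the presence
#' bonus added to tf whenever tf > 0 (default 5).
#'
#' @param delta Presence bonus, `>= 0`.
#' @param mu Dirichlet smoothing parameter, `> 0`.
#' @return A list of class `ds_psd_params`.
#' @export
psd_params <- function(delta = 5, mu = 2500) {
  stopifnot(is.numeric(delta), delta >= 0, is.numeric(mu), mu > 0)
  structure(list(delta = delta, mu = mu), class = "ds_psd_params")
}

#' PSD weight of one term in one document
#'
#' Computes, in natural log,
#' `log( (I(tf > 0) * (tf + delta) + mu * cf / coll_len) / (doc_len + mu) )`.
#' A term that occurs nowhere in the collection (`cf = 0` and `tf = 0`) has no
#' finite weight; `NA_real_` is returned as the out-of-vocabulary signal and
#' callers skip the term.
#'
#' @param tf Term frequency in the document.
#' @param cf Collection frequency of the term.
#' @param doc_len Document token length |D|.
#' @param coll_len Collection token count |C| (> 0).
#' @param params A [psd_params()] object.
#' @return Numeric weight, or `NA_real_` for an out-of-vocabulary term.
#' @export
#' @examples
#' psd_term_weight(1, 1, 3, 5)   # log(506/2503)
#' psd_term_weight(0, 1, 3, 5)   # log(500/2503)
psd_term_weight <- function(tf, cf, doc_len, coll_len, params = psd_params()) {
  stopifnot(coll_len > 0)
  if (cf == 0 && tf == 0) return(NA_real_)
  num <- (tf > 0) * (tf + params$delta) + params$mu * cf / coll_len
  log(num / (doc_len + params$mu))
}

#' PSD score of a document for a token multiset
#'
#' The sum of [psd_term_weight()] over the query tokens; a token occurring
#' twice in the query contributes twice. Out-of-vocabulary tokens are skipped.
#'
#' @param tokens Analyzed query tokens (ordered multiset; empty gives 0).
#' @param doc_id Document identifier.
#' @param index A `ds_index`.
#' @param params A [psd_params()] object.
#' @return Numeric score.
#' @export
psd_score <- function(tokens, doc_id, index, params = psd_params()) {
  if (length(tokens) == 0L) return(0)
  dl <- index$doc_len[[doc_id]]
  s <- 0
  for (t in tokens) {
    i <- match(t, names(index$cf))
    if (is.na(i)) next                         # OOV: skip
    cf <- index$cf[[i]]
    w <- psd_term_weight(doc_tf(index, t, doc_id), cf, dl, index$coll_len, params)
    if (!is.na(w)) s <- s + w
  }
  s
}

rescore_candidates <- function(candidates, tokens, index, params, tag) {
  topic <- if (nrow(candidates)) candidates$topic[[1L]] else "?"
  docs <- candidates$doc_id
  if (length(tokens) == 0L) {
    # Degenerate query: nothing to score; return candidates in doc_id order.
    return(ranked_list(topic, sort(docs), rep(0, length(docs)), tag = tag))
  }
  scores <- vapply(docs, function(d) psd_score(tokens, d, index, params), 0)
  ranked_list(topic, docs, scores, tag = tag)
}

#' Re-rank candidates with PSD over all question words
#'
#' The question is passed through the index analyzer (so stopwords the index
#' cannot match are removed) and every candidate is re-scored with
#' [psd_score()]; the output is the same document set reordered by descending
#' score, ties broken by ascending `doc_id`.
#'
#' @param question Free-text question.
#' @param candidates A `ds_ranked_list` of stage-1 candidates.
#' @param index A `ds_index`.
#' @param params A [psd_params()] object.
#' @param tag Method tag.
#' @return A `ds_ranked_list` over the same documents.
#' @export
rerank_psd_allwords <- function(question, candidates, index,
                                params = psd_params(), tag = "psd-allwords") {
  tokens <- index_analyze(index, question)
  rescore_candidates(candidates, tokens, index, params, tag)
}

#' Dictionary concept recognizer
#'
#' The default [rerank_psd_keywords()] recognizer: reduces the question to
#' keywords, segments them against the expansion dictionary, and returns the
#' deduplicated surface forms of the concepts found in the dictionary
#' (out-of-dictionary words are not treated as recognized concepts).
#'
#' @param dictionary A [read_dictionary()] object.
#' @return A function `question -> character vector of concept phrases`.
#' @export
dictionary_recognizer <- function(dictionary = read_dictionary()) {
  force(dictionary)
  function(question) {
    kw <- remove_stopwords(question)
    concepts <- map_concepts(kw, dictionary, expand = TRUE)
    in_dict <- vapply(concepts, function(con)
      normalize_phrase(con$surface) %in% names(dictionary), TRUE)
    unique(vapply(concepts[in_dict], `[[`, "", "surface"))
  }
}

#' Re-rank candidates with PSD over recognized concepts only
#'
#' As [rerank_psd_allwords()] but the query token multiset is built from the
#' concept phrases a recognizer extracts from the question (duplicates removed
#' at the concept level), eliminating the influence of uninformative question
#' words. If no concept is recognized, candidates are returned in ascending
#' `doc_id` order with score 0.
#'
#' @inheritParams rerank_psd_allwords
#' @param recognizer A function `question -> character vector of concept
#'   phrases`, e.g. [dictionary_recognizer()].
#' @return A `ds_ranked_list` over the same documents.
#' @export
rerank_psd_keywords <- function(question, candidates, index,
                                recognizer = dictionary_recognizer(),
                                params = psd_params(), tag = "psd-keywords") {
  phrases <- unique(recognizer(question))
  tokens <- unlist(lapply(phrases, function(p) index_analyze(index, p)))
  rescore_candidates(candidates, tokens, index, params, tag)
}

#' Surrogate-document provider backed by fixture files
#'
#' Reads per-topic surrogate documents from a directory: file
#' `<topic_id>.txt`, one document per paragraph (paragraphs separated by blank
#' lines). Stands behind the same interface a live web-search adapter would
#' implement: a function `(topic_id, question) -> character vector of
#' documents`.
#'
#' @param dir Directory of fixture files.
#' @return A provider function.
#' @export
fixture_surrogate_provider <- function(dir) {
  force(dir)
  function(topic_id, question = NULL) {
    f <- file.path(dir, paste0(topic_id, ".txt"))
    if (!file.exists(f)) return(character())
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    docs <- strsplit(txt, "\n\\s*\n")[[1L]]
    docs <- trimws(docs)
    docs[nzchar(docs)]
  }
}

#' Snippet-based query expansion re-ranking (SQEM)
#'
#' Concatenates the first `k` surrogate documents the provider returns for
#' the topic into one text, analyzes it with the index analyzer, and re-scores
#' the candidates with PSD using the resulting token multiset: the surrogate's
#' vocabulary and term frequencies replace the question's.
#'
#' @inheritParams rerank_psd_allwords
#' @param topic_id Topic identifier handed to the provider.
#' @param provider A surrogate provider, e.g. [fixture_surrogate_provider()].
#' @param k Number of surrogate documents to concatenate (default 10).
#' @return A `ds_ranked_list` over the same documents.
#' @export
rerank_sqem <- function(question, candidates, index, provider, topic_id = NULL,
                        k = 10L, params = psd_params(), tag = "sqem") {
  if (is.null(topic_id)) topic_id <- if (nrow(candidates)) candidates$topic[[1L]] else "?"
  docs <- provider(topic_id, question)
  if (length(docs) == 0L)
    stop("surrogate provider returned no documents for topic ", topic_id)
  surrogate <- paste(utils::head(docs, k), collapse = " ")
  tokens <- index_analyze(index, surrogate)
  rescore_candidates(candidates, tokens, index, params, tag)
}

#' Reciprocal-rank ensemble
#'
#' Fuses two or more ranked lists over the same topic: each document in the
#' union scores the mean over input lists of `1/rank` (0 for a list it is
#' absent from), and documents are reordered by descending mean, ties broken
#' by ascending `doc_id`. The score lies in (0, 1] and equals 1 exactly when
#' the document is ranked first in every list.
#'
#' @param lists A list of `>= 2` `ds_ranked_list`s sharing a topic.
#' @param tag Method tag.
#' @return A `ds_ranked_list` over the union of documents.
#' @export
ensemble <- function(lists, tag = "ensemble") {
  if (length(lists) < 2L) stop("ensemble needs at least 2 ranked lists")
  topics <- unique(vapply(lists, function(l) if (nrow(l)) l$topic[[1L]] else NA_character_, ""))
  topics <- topics[!is.na(topics)]
  if (length(topics) > 1L) stop("ensemble inputs must share one topic, got: ",
                                paste(topics, collapse = ", "))
  docs <- unique(unlist(lapply(lists, `[[`, "doc_id")))
  score <- vapply(docs, function(d) {
    mean(vapply(lists, function(l) {
      r <- l$rank[l$doc_id == d]
      if (length(r)) 1 / r[[1L]] else 0
    }, 0))
  }, 0)
  ranked_list(if (length(topics)) topics else "?", docs, score, tag = tag)
}
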