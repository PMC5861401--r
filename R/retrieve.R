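# Stage-1 candidate generation: Boolean concept matching with a minimum-match
# cascade. Documents are tiered by how many query concepts they express
# (higher tiers first, the cascade from "all concepts" down to the query's
# floor), ordered within tiers by a BM25 base score, and truncated to a cap.

#' Construct a ranked list
#'
#' Ordered retrieval results for one topic. Ranks are contiguous from 1,
#' scores non-increasing, ties broken by ascending `doc_id`, duplicates
#' forbidden.
#'
#' @param topic_id Topic identifier.
#' @param doc_ids Document identifiers.
#' @param scores Numeric scores, same length.
#' @param tag Method tag (written into TREC run files).
#' @param sort Sort by descending score / ascending doc_id first? If `FALSE`
#'   the input order must already satisfy the invariants.
#' @return An object of class `ds_ranked_list`: a `data.frame` with columns
#'   `topic`, `doc_id`, `rank`, `score` and a `tag` attribute.
#' @export
ranked_list <- function(topic_id, doc_ids, scores, tag = "run", sort = TRUE) {
  stopifnot(length(doc_ids) == length(scores))
  doc_ids <- as.character(doc_ids)
  if (anyDuplicated(doc_ids)) stop("duplicate doc_id in ranked list for topic ", topic_id)
  if (sort) {
    o <- order(-scores, doc_ids, method = "radix")
    doc_ids <- doc_ids[o]; scores <- scores[o]
  } else if (is.unsorted(rev(scores))) {
    stop("scores must be non-increasing")
  }
  out <- data.frame(topic = rep(as.character(topic_id), length(doc_ids)),
                    doc_id = doc_ids,
                    rank = seq_along(doc_ids),
                    score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  attr(out, "tag") <- tag
  attr(out, "topic") <- as.character(topic_id)
  class(out) <- c("ds_ranked_list", "data.frame")
  out
}

#' @export
print.ds_ranked_list <- function(x, n = 10L, ...) {
  cat("<ranked_list> topic ", if (nrow(x)) x$topic[[1L]] else "?", ", ",
      nrow(x), " entries, tag ", attr(x, "tag") %||% "run", "\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}

# Documents containing the analyzed token sequence `toks` contiguously within
# a single field.
phrase_docs <- function(index, toks) {
  if (length(toks) == 0L) return(character())
  cand <- term_docs(index, toks[[1L]])
  for (t in toks[-1L]) {
    if (length(cand) == 0L) return(character())
    cand <- intersect(cand, term_docs(index, t))
  }
  if (length(toks) == 1L) return(cand)
  cand[vapply(cand, function(doc) {
    any(vapply(index$doc_tokens[[doc]], function(ft) {
      L <- length(toks)
      if (length(ft) < L) return(FALSE)
      for (i in seq_len(length(ft) - L + 1L))
        if (ft[[i]] == toks[[1L]] && all(ft[i:(i + L - 1L)] == toks)) return(TRUE)
      FALSE
    }, TRUE))
  }, TRUE)]
}

# Documents whose stored exact-group field value equals the representation
# (case-insensitive, whole value).
exact_docs <- function(index, rep) {
  val <- tolower(trimws(rep))
  ids <- index$doc_ids
  ids[vapply(ids, function(doc) {
    ev <- index$exact_values[[doc]]
    !is.null(ev) && val %in% ev
  }, TRUE)]
}

# All documents expressing a concept through any of its representations.
concept_doc_set <- function(index, con) {
  docs <- character()
  reps <- unique(c(con$surface, con$representations))
  for (rep in reps) {
    toks <- index_analyze(index, rep)
    docs <- union(docs, phrase_docs(index, toks))
    docs <- union(docs, exact_docs(index, rep))
  }
  docs
}

#' Does a document express a concept?
#'
#' `TRUE` iff any representation of the concept (or its surface form),
#' analyzed with the index analyzer, occurs as a contiguous token sequence in
#' one in-scope field of the document, or equals the full value of one of its
#' exact-group fields.
#'
#' @param index A `ds_index`.
#' @param con A `ds_concept`.
#' @param doc_id Document identifier.
#' @return Logical scalar.
#' @export
match_concept <- function(index, con, doc_id) {
  for (rep in unique(c(con$surface, con$representations))) {
    ev <- index$exact_values[[doc_id]]
    if (!is.null(ev) && tolower(trimws(rep)) %in% ev) return(TRUE)
    toks <- index_analyze(index, rep)
    if (length(toks) == 0L) next
    ok <- FALSE
    for (ft in index$doc_tokens[[doc_id]]) {
      L <- length(toks)
      if (length(ft) < L) next
      for (i in seq_len(length(ft) - L + 1L)) {
        if (all(ft[i:(i + L - 1L)] == toks)) { ok <- TRUE; break }
      }
      if (ok) break
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' BM25 base score
#'
#' Okapi BM25 (`k1 = 1.2`, `b = 0.75`, Lucene-style non-negative idf) of a
#' document against a set of analyzed query terms. This is the within-tier
#' ordering score of the cascade; the tiering itself carries the Boolean
#' semantics.
#'
#' @param index A `ds_index`.
#' @param terms Character vector of analyzed terms (deduplicated internally).
#' @param doc_id Document identifier.
#' @param k1,b BM25 parameters.
#' @return Numeric score (0 when no term occurs in the document).
#' @export
base_score <- function(index, terms, doc_id, k1 = 1.2, b = 0.75) {
  terms <- unique(terms)
  if (length(terms) == 0L) return(0)
  N <- index$n_docs
  avgdl <- index$coll_len / N
  dl <- index$doc_len[[doc_id]]
  s <- 0
  for (t in terms) {
    tf <- doc_tf(index, t, doc_id)
    if (tf == 0) next
    df <- index$df[[t]]
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl / avgdl))
  }
  s
}

# Vectorized BM25 over many documents at once; same scores as base_score(),
# one postings pass per term instead of one per (term, doc) pair.
bm25_bulk <- function(index, terms, docs, k1 = 1.2, b = 0.75) {
  terms <- unique(terms)
  N <- index$n_docs
  avgdl <- index$coll_len / N
  dl <- index$doc_len[docs]
  s <- stats::setNames(numeric(length(docs)), docs)
  for (t in terms) {
    p <- index$postings[[t]]
    if (is.null(p)) next
    i <- match(names(p), docs)
    sel <- !is.na(i)
    if (!any(sel)) next
    tf <- unname(p[sel]); i <- i[sel]
    df <- length(p)
    idf <- log(1 + (N - df + 0.5) / (df + 0.5))
    s[i] <- s[i] + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * dl[i] / avgdl))
  }
  s
}

#' Minimum-match cascade retrieval
#'
#' Partitions matching documents into tiers by the number of satisfied
#' concepts (from all `n` down to the query's `minimum_match` floor, at least
#' 1), concatenates tiers in decreasing order, orders within tiers by BM25
#' then ascending `doc_id`, and truncates to `cap` entries. The reported score
#' flattens the (tier, base score) pair into one sortable real:
#' `matched_count + bm25 / (1 + bm25)`, the second summand lying in `[0, 1)`
#' so tiers never interleave.
#'
#' @param index A `ds_index`.
#' @param query A `ds_concept_query` with at least one concept (an empty
#'   concept list, or `minimum_match = 0`, yields an empty list).
#' @param cap Maximum number of results (default 5000).
#' @param tag Method tag for the output.
#' @return A `ds_ranked_list`.
#' @export
retrieve_cascade <- function(index, query, cap = 5000L, tag = "boolean") {
  n <- length(query$concepts)
  if (n == 0L || query$minimum_match == 0L)
    return(ranked_list(query$topic_id, character(), numeric(), tag = tag))
  floor_m <- max(1L, query$minimum_match)
  sets <- lapply(query$concepts, function(con) concept_doc_set(index, con))
  all_docs <- unique(unlist(sets))
  if (length(all_docs) == 0L)
    return(ranked_list(query$topic_id, character(), numeric(), tag = tag))
  counts <- rowSums(vapply(sets, function(s) all_docs %in% s,
                           logical(length(all_docs))))
  keep <- counts >= floor_m
  docs <- all_docs[keep]
  counts <- counts[keep]
  if (length(docs) == 0L)
    return(ranked_list(query$topic_id, character(), numeric(), tag = tag))
  union_terms <- unique(unlist(lapply(query$concepts, function(con)
    unlist(lapply(unique(c(con$surface, con$representations)),
                  function(r) index_analyze(index, r))))))
  bm <- bm25_bulk(index, union_terms, docs)
  score <- counts + bm / (1 + bm)
  rl <- ranked_list(query$topic_id, docs, score, tag = tag)
  if (nrow(rl) > cap) {
    tg <- attr(rl, "tag")
    rl <- rl[seq_len(cap), , drop = FALSE]
    rownames(rl) <- NULL
    attr(rl, "tag") <- tg
    attr(rl, "topic") <- query$topic_id
    class(rl) <- c("ds_ranked_list", "data.frame")
  }
  rl
}
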