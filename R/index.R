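# Inverted index over analyzed fields. Exposes exactly the collection
# statistics the retrieval models consume: per-document term frequency tf
# (summed across all in-scope fields, the document treated as one unit),
# collection frequency cf, document token length |D| and collection token
# count |C|. Token positions are kept per field so multi-token concept
# representations can be matched by adjacency within one field.

#' Build an inverted index
#'
#' Every in-scope `string`/`exact` field of every record is analyzed with the
#' packaged analyzer chain and indexed; `exact`-group fields are additionally
#' stored unanalyzed (lowercased) for exact matching. `other`-group fields
#' (dates and the like) are skipped. Scope is controlled by the
#' [field_schema()]: restrict to standard fields or not, include the
#' `additional.*` namespace or not.
#'
#' @param corpus A nonempty `ds_corpus`.
#' @param schema A `ds_schema`; the default indexes all metadata fields plus
#'   `additional.*`.
#' @param protected A [protected_terms()] set, or `NULL`.
#' @param stopwords Indexing stopword list.
#' @return An object of class `ds_index`.
#' @export
build_index <- function(corpus, schema = field_schema(use_standard_fields = FALSE),
                        protected = NULL,
                        stopwords = load_stopwords("pubmed")) {
  if (!inherits(corpus, "ds_corpus") || length(corpus) == 0L)
    stop("corpus must be a nonempty ds_corpus")
  doc_ids <- names(corpus)
  doc_tokens <- vector("list", length(corpus))
  exact_values <- vector("list", length(corpus))
  names(doc_tokens) <- names(exact_values) <- doc_ids

  chunks <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    rec <- corpus[[i]]
    paths <- fields_in_scope(rec, schema)
    ftoks <- lapply(paths, function(p) analyze(rec$fields[[p]], protected, stopwords))
    names(ftoks) <- paths
    ftoks <- ftoks[lengths(ftoks) > 0L]
    doc_tokens[[i]] <- ftoks
    ex <- paths[rec$groups[paths] == "exact"]
    if (length(ex))
      exact_values[[i]] <- stats::setNames(tolower(trimws(rec$fields[ex])), ex)
    all_toks <- unlist(ftoks, use.names = FALSE)
    if (length(all_toks)) {
      tf <- table(all_toks)
      chunks[[i]] <- data.table::data.table(term = names(tf), doc = rec$doc_id,
                                            tf = as.numeric(tf))
    }
  }
  post <- data.table::rbindlist(chunks[!vapply(chunks, is.null, TRUE)])
  if (nrow(post) == 0L) stop("index is empty: no in-scope tokens in corpus")
  data.table::setorder(post, term, doc)

  postings <- lapply(split(post, by = "term", keep.by = FALSE),
                     function(d) stats::setNames(d$tf, d$doc))
  doc_len <- vapply(doc_tokens, function(f) sum(lengths(f)), 0)
  idx <- structure(list(
    postings = postings,
    cf = vapply(postings, sum, 0),
    df = vapply(postings, length, 0L),
    doc_len = doc_len,
    coll_len = sum(doc_len),
    n_docs = length(corpus),
    doc_ids = doc_ids,
    doc_tokens = doc_tokens,
    exact_values = exact_values,
    stopwords = stopwords,
    protected = protected,
    schema = schema,
    version = "datasearch-index-1"
  ), class = "ds_index")
  idx
}

#' @export
print.ds_index <- function(x, ...) {
  cat("<ds_index> ", x$n_docs, " docs, ", length(x$postings), " terms, |C| = ",
      x$coll_len, "\n", sep = "")
  invisible(x)
}

#' Collection statistics for a term
#'
#' @param index A `ds_index`.
#' @param term An analyzed term (single token).
#' @return Named numeric vector `c(cf = ..., coll_len = ...)`; `cf` is 0 for
#'   out-of-vocabulary terms, `coll_len` is the constant |C| of the index.
#' @export
index_stats <- function(index, term) {
  i <- match(term, names(index$cf))
  c(cf = if (is.na(i)) 0 else index$cf[[i]], coll_len = index$coll_len)
}

# tf of a term in one document (0 if absent). `term` must be analyzed.
doc_tf <- function(index, term, doc_id) {
  p <- index$postings[[term]]
  if (is.null(p)) return(0)
  i <- match(doc_id, names(p))
  if (is.na(i)) 0 else p[[i]]
}

# doc ids containing a term
term_docs <- function(index, term) {
  p <- index$postings[[term]]
  if (is.null(p)) character() else names(p)
}

#' Write an index to a versioned JSON file
#'
#' A documented single-file persistence format: one JSON object with a
#' `version` header, the collection statistics and the per-document per-field
#' token streams (from which postings are rebuilt on load).
#'
#' @param index A `ds_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  payload <- list(
    version = index$version,
    stopwords = index$stopwords,
    protected = lapply(unclass(index$protected %||% list()), identity),
    schema = unclass(index$schema),
    doc_tokens = index$doc_tokens,
    exact_values = index$exact_values
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null"), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read an index written by [write_index()]
#'
#' @param path Path to the index file.
#' @return A `ds_index`.
#' @export
read_index <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = FALSE)
  if (!identical(payload$version, "datasearch-index-1"))
    stop("unsupported index version in ", path)
  doc_tokens <- lapply(payload$doc_tokens, function(f)
    lapply(f, function(t) as.character(unlist(t))))
  exact_values <- lapply(payload$exact_values, function(e)
    if (length(e)) unlist(e) else NULL)
  chunks <- list()
  for (doc in names(doc_tokens)) {
    toks <- unlist(doc_tokens[[doc]], use.names = FALSE)
    if (length(toks)) {
      tf <- table(toks)
      chunks[[doc]] <- data.table::data.table(term = names(tf), doc = doc,
                                              tf = as.numeric(tf))
    }
  }
  post <- data.table::rbindlist(chunks)
  data.table::setorder(post, term, doc)
  postings <- lapply(split(post, by = "term", keep.by = FALSE),
                     function(d) stats::setNames(d$tf, d$doc))
  doc_len <- vapply(doc_tokens, function(f) sum(lengths(f)), 0)
  prot <- payload$protected
  prot <- if (length(prot)) structure(lapply(prot, function(p) as.character(unlist(p))),
                                      class = "ds_protected") else NULL
  schema <- payload$schema
  structure(list(
    postings = postings,
    cf = vapply(postings, sum, 0),
    df = vapply(postings, length, 0L),
    doc_len = doc_len,
    coll_len = sum(doc_len),
    n_docs = length(doc_tokens),
    doc_ids = names(doc_tokens),
    doc_tokens = doc_tokens,
    exact_values = exact_values,
    stopwords = as.character(unlist(payload$stopwords)),
    protected = prot,
    schema = structure(list(standard_fields = schema$standard_fields,
                            use_standard_fields = isTRUE(schema$use_standard_fields),
                            use_additional_fields = isTRUE(schema$use_additional_fields)),
                       class = "ds_schema"),
    version = payload$version
  ), class = "ds_index")
}

# Analyze a query-side string with the index's own analyzer configuration.
index_analyze <- function(index, text) {
  analyze(text, protected = index$protected, stopwords = index$stopwords)
}
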