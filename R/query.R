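# Query generation: reduce a free-text question to keywords, segment the
# keywords into dictionary concepts, expand each concept to its synonym
# representations and assemble a nested Boolean query with a minimum-match
# parameter.

#' Remove uninformative words from a question
#'
#' Drops every word whose lowercased core (edge punctuation stripped) is in
#' the general-English stopword list or in the self-defined dataset-search
#' boilerplate list ("data", "dataset", "find", "across", ...). Surviving
#' words keep their original surface forms, including hyphens, and their
#' original order.
#'
#' @param question Free-text question.
#' @param extra Additional stopwords (lowercase) to remove.
#' @return The filtered question as a single string (possibly empty).
#' @export
#' @examples
#' remove_stopwords(
#'   "find data of all types related to TGF-beta signaling pathway across all databases")
remove_stopwords <- function(question, extra = character()) {
  stopset <- c(load_stopwords("english"), load_stopwords("question"), tolower(extra))
  words <- strsplit(trimws(question), "\\s+")[[1L]]
  if (length(words) == 0L || identical(words, "")) return("")
  core <- tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", words))
  keep <- nzchar(core) & !(core %in% stopset)
  paste(words[keep], collapse = " ")
}

#' Construct a concept
#'
#' A concept couples a surface form with its ordered representations
#' (synonyms/expansions, possibly including the surface form itself). A
#' document expresses the concept if any representation occurs in it (see
#' [match_concept()]).
#'
#' @param surface Surface form as it appeared in the question.
#' @param representations Nonempty character vector of representation phrases;
#'   duplicates are removed, order preserved.
#' @return An object of class `ds_concept`.
#' @export
concept <- function(surface, representations = surface) {
  representations <- unique(as.character(representations))
  if (length(representations) == 0L) stop("concept needs >= 1 representation")
  structure(list(surface = surface, representations = representations),
            class = "ds_concept")
}

#' @export
print.ds_concept <- function(x, ...) {
  cat("<concept> ", x$surface, " := {",
      paste(x$representations, collapse = " | "), "}\n", sep = "")
  invisible(x)
}

#' Segment keywords into dictionary concepts
#'
#' Greedy longest-match segmentation left-to-right against the expansion
#' dictionary, with hyphen/space-insensitive phrase lookup (so `"TGF-beta"`
#' matches the entry `"tgf beta"`). Out-of-dictionary words become singleton
#' concepts whose only representation is themselves. The concatenated surface
#' forms of the result cover every input word exactly once.
#'
#' @param keywords Keyword string (typically the output of
#'   [remove_stopwords()]).
#' @param dictionary A [read_dictionary()] object.
#' @param expand If `FALSE`, dictionary expansions are suppressed and every
#'   concept's only representation is its surface form (the query-expansion
#'   ablation switch).
#' @return A list of `ds_concept`s (possibly empty).
#' @export
map_concepts <- function(keywords, dictionary = read_dictionary(), expand = TRUE) {
  words <- strsplit(trimws(keywords), "\\s+")[[1L]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) return(list())
  max_key <- if (length(dictionary)) max(lengths(strsplit(names(dictionary), " ", fixed = TRUE))) else 1L
  concepts <- list()
  i <- 1L
  while (i <= length(words)) {
    matched <- FALSE
    for (L in seq(min(max_key, length(words) - i + 1L), 1L)) {
      surface <- paste(words[i:(i + L - 1L)], collapse = " ")
      key <- normalize_phrase(surface)
      reps <- dictionary[[key]]
      if (!is.null(reps)) {
        concepts[[length(concepts) + 1L]] <-
          if (expand) concept(surface, reps) else concept(surface)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      concepts[[length(concepts) + 1L]] <- concept(words[[i]])
      i <- i + 1L
    }
  }
  concepts
}

#' Assemble a nested Boolean concept query
#'
#' Representations of one concept are OR-ed; the query at minimum-match level
#' `m` requires at least `m` concepts to be present in a document. `m = 0` is
#' allowed and matches nothing by convention.
#'
#' @param topic_id Topic identifier.
#' @param concepts List of `ds_concept`s.
#' @param minimum_match Integer `m`, `0 <= m <= length(concepts)`.
#' @return An object of class `ds_concept_query`.
#' @export
build_boolean_query <- function(topic_id, concepts, minimum_match = length(concepts)) {
  minimum_match <- as.integer(minimum_match)
  if (minimum_match < 0L || minimum_match > length(concepts))
    stop("minimum_match must be between 0 and the number of concepts (",
         length(concepts), "), got ", minimum_match)
  structure(list(topic_id = as.character(topic_id), concepts = concepts,
                 minimum_match = minimum_match),
            class = "ds_concept_query")
}

#' @export
print.ds_concept_query <- function(x, ...) {
  cat("<concept_query> topic ", x$topic_id, ", minimum_match ", x$minimum_match,
      "\n", sep = "")
  for (con in x$concepts) print(con)
  invisible(x)
}

#' Generate a query from a free-text question
#'
#' Convenience wrapper: stopword removal, concept mapping, Boolean assembly.
#' The default `minimum_match = 1` encodes the retrieval rule that a dataset
#' is retrieved if at least one concept is present; [retrieve_cascade()]
#' relaxes tier by tier from all concepts down to this floor.
#'
#' @inheritParams map_concepts
#' @param topic_id Topic identifier.
#' @param question Free-text question.
#' @param minimum_match Cascade floor (clamped to the number of concepts).
#' @return A `ds_concept_query`.
#' @export
generate_query <- function(topic_id, question, dictionary = read_dictionary(),
                           expand = TRUE, minimum_match = 1L) {
  kw <- remove_stopwords(question)
  concepts <- map_concepts(kw, dictionary, expand = expand)
  build_boolean_query(topic_id, concepts,
                      minimum_match = min(minimum_match, length(concepts)))
}

#' Serialize a concept query as JSON
#' @param query A `ds_concept_query`.
#' @return A JSON string.
#' @export
query_to_json <- function(query) {
  jsonlite::toJSON(list(
    topic_id = query$topic_id,
    minimum_match = query$minimum_match,
    concepts = lapply(query$concepts, function(con)
      list(surface = con$surface, representations = con$representations))
  ), auto_unbox = TRUE, pretty = TRUE)
}
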