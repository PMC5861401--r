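# Packaged plain-text resources: stopword lists, the offline expansion
# dictionary and the protected-term list. All are versioned static files under
# inst/extdata; loaders strip '#' comments and blank lines.

res_path <- function(file) {
  p <- system.file("extdata", file, package = "datasearch")
  if (!nzchar(p)) stop("packaged resource not found: ", file)
  p
}

read_resource_lines <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Load a packaged stopword list
#'
#' Two lists ship with the package: `"pubmed"`, the indexing-side list used by
#' the analyzer chain, and `"english"`, the general-English list used (together
#' with `"question"`, the dataset-search boilerplate list) when free-text
#' questions are reduced to keywords.
#'
#' @param source One of `"pubmed"`, `"english"`, `"question"`.
#' @return A character vector of lowercase stopwords.
#' @export
#' @examples
#' "the" %in% load_stopwords("pubmed")
load_stopwords <- function(source = c("pubmed", "english", "question")) {
  if (!is.character(source) || length(source) != 1L ||
      !source %in% c("pubmed", "english", "question")) {
    stop("unknown stopword resource: ", paste(source, collapse = ", "))
  }
  file <- switch(source,
    pubmed   = "stopwords_pubmed.txt",
    english  = "stopwords_english.txt",
    question = "stopwords_question.txt"
  )
  tolower(read_resource_lines(res_path(file)))
}

#' Read a concept-expansion dictionary
#'
#' The dictionary is a plain-text resource with one entry per line,
#' `phrase<TAB>expansion1|expansion2|...`. Phrase keys are matched
#' case-insensitively and hyphen/space-insensitively, so `"TGF-beta"` finds the
#' entry `"tgf beta"`.
#'
#' @param path Path to a dictionary file; the default is the packaged core
#'   dictionary.
#' @return An object of class `ds_dictionary`: a named list mapping normalized
#'   phrase keys to character vectors of expansions, with the original phrases
#'   in `attr(, "phrases")`.
#' @export
read_dictionary <- function(path = res_path("dictionary_core.tsv")) {
  lines <- read_resource_lines(path)
  entries <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(entries) != 2L
  if (any(bad)) stop("malformed dictionary line(s): ", paste(lines[bad], collapse = "; "))
  phrases <- vapply(entries, `[[`, "", 1L)
  keys <- normalize_phrase(phrases)
  if (anyDuplicated(keys)) stop("duplicate dictionary phrase: ",
                                paste(phrases[duplicated(keys)], collapse = ", "))
  reps <- lapply(entries, function(e) unique(strsplit(e[[2L]], "|", fixed = TRUE)[[1L]]))
  dict <- stats::setNames(reps, keys)
  attr(dict, "phrases") <- stats::setNames(phrases, keys)
  class(dict) <- "ds_dictionary"
  dict
}

#' @export
print.ds_dictionary <- function(x, ...) {
  cat("<ds_dictionary> ", length(x), " phrases, max key length ",
      if (length(x)) max(lengths(strsplit(names(x), " ", fixed = TRUE))) else 0L,
      " words\n", sep = "")
  invisible(x)
}

# Normalize a phrase for dictionary lookup: lowercase, hyphens to spaces,
# collapse whitespace.
normalize_phrase <- function(x) {
  x <- tolower(x)
  x <- gsub("[-‐‑]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Load a protected-term set
#'
#' Protected terms (MeSH headings and their entry terms) are exempt from the
#' light stemmer so that, e.g., `"Neoplasms"` is indexed verbatim rather than
#' as `"neoplasm"`. Multi-word phrases are honored: their constituent tokens
#' are flagged unstemmable when the phrase occurs in text.
#'
#' @param terms A character vector of terms, or `NULL` for the packaged sample
#'   list.
#' @return An object of class `ds_protected`: a list of lowercase token
#'   vectors, one per protected phrase.
#' @export
protected_terms <- function(terms = NULL) {
  if (is.null(terms)) terms <- read_resource_lines(res_path("protected_terms.txt"))
  terms <- terms[nzchar(trimws(terms))]
  toks <- lapply(terms, function(t) fold_ascii(tolower(ds_tokenize(t))))
  toks <- toks[lengths(toks) > 0L]
  toks <- unique(toks)
  structure(toks, class = "ds_protected")
}
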