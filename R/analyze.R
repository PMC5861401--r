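# The deterministic analyzer chain shared by the index side and the query
# side: word tokenization, possessive stripping, lowercasing, ASCII folding,
# stopword removal, then a light English stemmer that protected phrases
# bypass. The chain order is fixed; analyze() is pure.

# Unicode-word tokenization: maximal runs of letters/digits, keeping interior
# apostrophes with the word so the possessive filter can see them.
ds_tokenize <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character())
  m <- gregexpr("[\\p{L}\\p{N}]+(?:['’][\\p{L}\\p{N}]+)*", text, perl = TRUE)
  regmatches(text, m)[[1L]]
}

# Strip a trailing possessive ('s or Unicode-apostrophe s), then drop any
# remaining apostrophes.
strip_possessive <- function(tokens) {
  tokens <- sub("['’][sS]$", "", tokens)
  gsub("['’]", "", tokens)
}

# Fold Latin diacritics to ASCII and drop every other non-ASCII character.
fold_ascii <- function(tokens) {
  out <- suppressWarnings(iconv(tokens, from = "UTF-8", to = "ASCII//TRANSLIT"))
  out[is.na(out)] <- vapply(tokens[is.na(out)], function(t) {
    t2 <- suppressWarnings(iconv(t, from = "UTF-8", to = "ASCII", sub = ""))
    if (is.na(t2)) "" else t2
  }, "")
  gsub("[^a-z0-9]", "", out)
}

#' Light English stemmer
#'
#' A conservative, frozen rule table covering plural classes only, in the
#' spirit of "light" stemming: `-ies -> -y`, `-sses -> -ss`, `-xes/-ches/-shes/
#' -zes/-oes -> drop -es`, otherwise drop a final `-s`. Words of three or fewer
#' characters, words ending in `-ss`, `-us`, `-is`, and tokens containing
#' digits are left unchanged. The rules are part of the package contract:
#' identical inputs always stem identically across versions.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of stemmed tokens.
#' @export
#' @examples
#' light_stem(c("genes", "pathway", "studies", "classes", "viruses"))
light_stem <- function(tokens) {
  vapply(tokens, function(w) {
    n <- nchar(w)
    if (n <= 3L || grepl("[0-9]", w)) return(w)
    if (grepl("ies$", w) && n > 4L) return(paste0(substr(w, 1L, n - 3L), "y"))
    if (grepl("sses$", w)) return(substr(w, 1L, n - 2L))
    if (grepl("(ss|us|is)$", w)) return(w)
    if (grepl("(x|ch|sh|z|o|us)es$", w)) return(substr(w, 1L, n - 2L))
    if (grepl("s$", w)) return(substr(w, 1L, n - 1L))
    w
  }, "", USE.NAMES = FALSE)
}

# Positions (logical vector) of tokens covered by any protected phrase,
# located by scanning the token stream for each phrase's token sequence.
protected_positions <- function(tokens, protected) {
  hit <- logical(length(tokens))
  if (length(tokens) == 0L || is.null(protected) || length(protected) == 0L) return(hit)
  for (ph in protected) {
    L <- length(ph)
    if (L == 0L || L > length(tokens)) next
    if (L == 1L) {
      hit[tokens == ph[[1L]]] <- TRUE
    } else {
      for (i in seq_len(length(tokens) - L + 1L)) {
        if (all(tokens[i:(i + L - 1L)] == ph)) hit[i:(i + L - 1L)] <- TRUE
      }
    }
  }
  hit
}

#' Analyze text into index/query tokens
#'
#' Applies the full analyzer chain in order: Unicode-word tokenization (split
#' on non-alphanumerics, interior apostrophes kept), trailing-possessive
#' stripping, lowercasing, ASCII folding (transliterate Latin diacritics, drop
#' other non-ASCII), stopword removal, and light English stemming. Tokens
#' covered by a protected phrase (matched on their lowercased surface forms
#' before stemming) bypass the stemmer.
#'
#' @param text A single character string.
#' @param protected A [protected_terms()] set, or `NULL`.
#' @param stopwords Character vector of stopwords to drop; defaults to the
#'   packaged PubMed indexing list. Use `character()` to keep everything.
#' @return A character vector of analyzed tokens (possibly empty).
#' @export
#' @examples
#' analyze("TGF-beta's pathway", stopwords = load_stopwords("pubmed"))
analyze <- function(text, protected = NULL,
                    stopwords = load_stopwords("pubmed")) {
  toks <- ds_tokenize(text)
  if (length(toks) == 0L) return(character())
  toks <- strip_possessive(toks)
  toks <- tolower(toks)
  toks <- fold_ascii(toks)
  keep <- nzchar(toks)
  toks <- toks[keep]
  if (length(toks) == 0L) return(character())
  prot <- protected_positions(toks, protected)
  keep <- !(toks %in% stopwords)
  toks <- toks[keep]
  prot <- prot[keep]
  if (length(toks) == 0L) return(character())
  toks[!prot] <- light_stem(toks[!prot])
  toks
}
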