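# Corpus model: reading DATS-like JSON metadata into MetadataRecord objects,
# field-group assignment, the per-repository standard-field schema, and
# merging of "additional information" (Summary / Title / Overall design texts
# harvested for a subset of datasets).

#' Construct a metadata record
#'
#' A record is one dataset's fielded metadata: an opaque `doc_id`, the
#' repository of origin, an ordered map of dot-separated field paths to text
#' values, and a field group per path. Groups drive indexing: `exact` fields
#' (controlled vocabularies such as MeSH terms) are additionally stored
#' unanalyzed for exact matching, `string` fields are analyzed free text, and
#' `other` fields (e.g. release dates) are not indexed.
#'
#' @param doc_id Unique document identifier.
#' @param fields Named character vector: field path -> text value.
#' @param repository Repository label.
#' @param groups Optional named character vector path -> group; missing paths
#'   are assigned by [assign_field_groups()].
#' @param exact_paths Field paths to treat as `exact` when auto-assigning.
#' @return An object of class `ds_record`.
#' @export
metadata_record <- function(doc_id, fields, repository = "unknown",
                            groups = NULL, exact_paths = character()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  fields <- unlist(fields)
  if (length(fields) == 0L) fields <- stats::setNames(character(), character())
  storage.mode(fields) <- "character"
  if (is.null(names(fields)) || any(!nzchar(names(fields))))
    stop("every field must have a nonempty path (record ", doc_id, ")")
  auto <- assign_field_groups(names(fields), exact_paths = exact_paths)
  if (!is.null(groups)) auto[names(groups)] <- groups
  if (!all(auto %in% c("exact", "string", "other")))
    stop("field groups must be exact/string/other")
  structure(list(doc_id = doc_id, repository = repository,
                 fields = fields, groups = auto),
            class = "ds_record")
}

#' Default field-group assignment
#'
#' Date-like paths become `other`, configured controlled-vocabulary paths
#' become `exact`, everything else (descriptions, titles, the
#' `additional.*` namespace) is `string`.
#'
#' @param paths Character vector of field paths.
#' @param exact_paths Paths to classify as `exact`.
#' @param other_pattern Regular expression for `other`-group paths.
#' @return Named character vector path -> group.
#' @export
assign_field_groups <- function(paths, exact_paths = character(),
                                other_pattern = "(date|released|lastmodified|timestamp)") {
  g <- rep("string", length(paths))
  g[grepl(other_pattern, tolower(paths))] <- "other"
  g[paths %in% exact_paths] <- "exact"
  stats::setNames(g, paths)
}

# Flatten a parsed JSON structure into a named character vector of
# dot-separated paths. Arrays of scalars are joined with a single space;
# arrays of objects are flattened element-wise and joined per sub-path.
flatten_fields <- function(x, prefix = "") {
  out <- list()
  add <- function(path, value) {
    value <- paste(value, collapse = " ")
    if (!nzchar(path)) path <- "value"
    if (!is.null(out[[path]])) out[[path]] <<- paste(out[[path]], value)
    else out[[path]] <<- value
  }
  walk <- function(x, prefix) {
    if (is.null(x)) return(invisible())
    if (is.list(x)) {
      nm <- names(x)
      if (is.null(nm) || all(!nzchar(nm))) {
        for (el in x) walk(el, prefix)              # array: merge under same path
      } else {
        for (i in seq_along(x)) {
          p <- if (nzchar(prefix)) paste(prefix, nm[[i]], sep = ".") else nm[[i]]
          walk(x[[i]], p)
        }
      }
    } else {
      x <- x[!is.na(x)]
      if (length(x)) add(prefix, as.character(x))
    }
  }
  walk(x, prefix)
  unlist(out)
}

parse_record_json <- function(obj, source = "<memory>", exact_paths = character()) {
  id <- NULL
  for (k in c("doc_id", "id", "identifier")) {
    v <- obj[[k]]
    if (!is.null(v) && length(v) == 1L && nzchar(as.character(v))) { id <- as.character(v); break }
  }
  if (is.null(id)) stop("document in ", source, " has no identifier field")
  repo <- if (!is.null(obj[["repository"]])) as.character(obj[["repository"]][[1L]]) else "unknown"
  body <- obj[setdiff(names(obj), c("doc_id", "id", "identifier", "repository"))]
  if (!is.null(body[["fields"]]) && is.list(body[["fields"]]) &&
      length(body) == 1L) body <- body[["fields"]]
  fields <- flatten_fields(body)
  metadata_record(id, fields, repository = repo, exact_paths = exact_paths)
}

#' Read a corpus of JSON metadata
#'
#' Accepts a directory of `.json`/`.jsonl` files, a single JSON file (one
#' object, or an array of objects), or a JSON-lines file with one document per
#' line. Nested objects are flattened to dot-separated field paths preserving
#' nesting order; scalar arrays are joined with single spaces. Malformed files
#' are reported by name and skipped; duplicate `doc_id`s are a hard error
#' naming the offending sources.
#'
#' @param path Directory or file path.
#' @param exact_paths Field paths to classify as `exact`.
#' @return An object of class `ds_corpus`: a list of `ds_record`s named by
#'   `doc_id`.
#' @export
read_corpus <- function(path, exact_paths = character()) {
  stopifnot(file.exists(path))
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.jsonl?$", full.names = TRUE)
  } else path
  if (length(files) == 0L) stop("no JSON files found under ", path)
  records <- list()
  origin <- character()
  for (f in files) {
    objs <- tryCatch(read_json_documents(f), error = function(e) {
      warning("skipping malformed JSON in ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    for (obj in objs) {
      rec <- parse_record_json(obj, source = basename(f), exact_paths = exact_paths)
      if (rec$doc_id %in% names(records)) {
        stop("duplicate doc_id '", rec$doc_id, "' in ", basename(f),
             " (first seen in ", origin[[rec$doc_id]], ")")
      }
      records[[rec$doc_id]] <- rec
      origin[[rec$doc_id]] <- basename(f)
    }
  }
  as_corpus(records)
}

# Parse one file as a JSON value (object or array of objects) or JSON-lines.
read_json_documents <- function(f) {
  txt <- readLines(f, encoding = "UTF-8", warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0L) return(list())
  whole <- paste(txt, collapse = "\n")
  parsed <- tryCatch(jsonlite::fromJSON(whole, simplifyVector = FALSE), error = function(e) NULL)
  if (!is.null(parsed)) {
    if (!is.null(names(parsed))) return(list(parsed))
    return(parsed)
  }
  # JSON-lines fallback: every line must parse on its own
  lapply(txt, function(line) jsonlite::fromJSON(line, simplifyVector = FALSE))
}

#' @export
as_corpus <- function(records) {
  stopifnot(all(vapply(records, inherits, TRUE, "ds_record")))
  ids <- vapply(records, `[[`, "", "doc_id")
  if (anyDuplicated(ids)) stop("duplicate doc_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  structure(stats::setNames(records, ids), class = "ds_corpus")
}

#' @export
print.ds_corpus <- function(x, ...) {
  nf <- sum(vapply(x, function(r) length(r$fields), 0L))
  cat("<ds_corpus> ", length(x), " records, ", nf, " fields, repositories: ",
      paste(unique(vapply(x, `[[`, "", "repository")), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a corpus to JSON-lines
#'
#' One object per line with `doc_id`, `repository` and the flattened `fields`
#' map; [read_corpus()] round-trips this format field-identically.
#'
#' @param corpus A `ds_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(r) {
    jsonlite::toJSON(list(doc_id = r$doc_id, repository = r$repository,
                          fields = as.list(r$fields)), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read additional-information records
#'
#' JSON-lines with objects `{doc_id, summary, title, overall_design}` (any
#' subset of the three text keys; at least one must be nonempty).
#'
#' @param path File path.
#' @return A list of additional-info entries.
#' @export
read_additional_info <- function(path) {
  objs <- read_json_documents(path)
  lapply(objs, function(o) {
    if (is.null(o$doc_id)) stop("additional-info entry without doc_id in ", basename(path))
    entry <- list(doc_id = as.character(o$doc_id),
                  summary = as.character(o$summary %||% ""),
                  title = as.character(o$title %||% ""),
                  overall_design = as.character(o$overall_design %||% ""))
    if (!any(nzchar(c(entry$summary, entry$title, entry$overall_design))))
      stop("additional-info entry for ", entry$doc_id, " has no nonempty text")
    entry
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge additional information into a corpus
#'
#' Matched records gain new `additional.summary` / `additional.title` /
#' `additional.overall_design` fields (group `string`); existing fields are
#' never overwritten, so the merge is idempotent. Extras referencing absent
#' `doc_id`s are counted and reported.
#'
#' @param corpus A `ds_corpus`.
#' @param extra A list of additional-info entries (see
#'   [read_additional_info()]).
#' @param quiet Suppress the unmatched-count message.
#' @return The enriched corpus (same record count and order).
#' @export
merge_additional_info <- function(corpus, extra, quiet = FALSE) {
  unmatched <- 0L
  for (e in extra) {
    rec <- corpus[[e$doc_id]]
    if (is.null(rec)) { unmatched <- unmatched + 1L; next }
    for (k in c("summary", "title", "overall_design")) {
      v <- e[[k]]
      if (is.null(v) || !nzchar(v)) next
      p <- paste0("additional.", k)
      if (p %in% names(rec$fields)) next      # never overwrite
      rec$fields[[p]] <- v
      rec$groups[[p]] <- "string"
    }
    corpus[[e$doc_id]] <- rec
  }
  if (unmatched > 0L && !quiet)
    message(unmatched, " additional-info entr",
            if (unmatched == 1L) "y" else "ies", " matched no record")
  corpus
}

#' Per-repository standard-field schema
#'
#' Declares which metadata fields are "standard fields" (the most informative
#' fields of each repository) and whether indexing should restrict itself to
#' them and/or include the `additional.*` namespace. When
#' `use_standard_fields` is `FALSE`, all metadata fields are in scope.
#'
#' @param standard_fields Either a character vector of field paths applied to
#'   every repository, or a named list repository -> character vector.
#' @param use_standard_fields Restrict indexing to the standard fields?
#' @param use_additional_fields Include `additional.*` fields?
#' @return An object of class `ds_schema`.
#' @export
field_schema <- function(standard_fields = NULL, use_standard_fields = TRUE,
                         use_additional_fields = TRUE) {
  structure(list(standard_fields = standard_fields,
                 use_standard_fields = isTRUE(use_standard_fields),
                 use_additional_fields = isTRUE(use_additional_fields)),
            class = "ds_schema")
}

standard_fields_for <- function(schema, repository) {
  sf <- schema$standard_fields
  if (is.null(sf)) return(NULL)
  if (is.list(sf)) return(sf[[repository]])
  sf
}

# Which of a record's fields are in indexing scope under a schema.
fields_in_scope <- function(record, schema) {
  paths <- names(record$fields)
  is_add <- startsWith(paths, "additional.")
  keep_meta <- !is_add
  if (schema$use_standard_fields) {
    std <- standard_fields_for(schema, record$repository)
    if (!is.null(std)) keep_meta <- keep_meta & paths %in% std
  }
  keep_add <- is_add & schema$use_additional_fields
  keep <- (keep_meta | keep_add) & record$groups[paths] != "other"
  paths[keep]
}

#' Validate a schema against a corpus
#'
#' Warns about configured standard-field paths that occur in no record of the
#' targeted repository.
#'
#' @param schema A `ds_schema`.
#' @param corpus A `ds_corpus`.
#' @return Invisibly, a character vector of missing paths.
#' @export
check_schema <- function(schema, corpus) {
  sf <- schema$standard_fields
  if (is.null(sf)) return(invisible(character()))
  repos <- unique(vapply(corpus, `[[`, "", "repository"))
  missing <- character()
  for (repo in repos) {
    std <- standard_fields_for(schema, repo)
    if (is.null(std)) next
    seen <- unique(unlist(lapply(corpus, function(r)
      if (r$repository == repo) names(r$fields) else NULL)))
    miss <- setdiff(std, seen)
    if (length(miss)) {
      warning("standard fields absent from repository ", repo, ": ",
              paste(miss, collapse = ", "), call. = FALSE)
      missing <- c(missing, miss)
    }
  }
  invisible(missing)
}
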