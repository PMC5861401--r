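# TREC-format plumbing: six-column run files and qrels with graded relevance
# 0/1/2, optionally carrying sampling metadata (judgment-pool membership with
# stratum labels) for the inferred measures. Files are whitespace-delimited
# and bit-compatible with the NIST tool conventions.

#' Write ranked lists as a TREC run file
#'
#' Six columns per line: `topic Q0 doc_id rank score tag`.
#'
#' @param runs A single `ds_ranked_list`, or a list of them (one per topic),
#'   or a run `data.frame` as returned by [read_run()].
#' @param path Output file path.
#' @param tag Overrides the per-list method tag when non-`NULL`.
#' @return `path`, invisibly.
#' @export
write_run <- function(runs, path, tag = NULL) {
  df <- as_run_df(runs, tag = tag)
  lines <- sprintf("%s Q0 %s %d %.6f %s",
                   df$topic, df$doc_id, df$rank, df$score, df$tag)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Normalize run inputs (ranked list(s) or data.frame) to one data.frame with
# topic/doc_id/rank/score/tag.
as_run_df <- function(runs, tag = NULL) {
  if (inherits(runs, "ds_ranked_list")) runs <- list(runs)
  if (is.data.frame(runs)) {
    df <- runs
    if (is.null(df$tag)) df$tag <- tag %||% "run"
  } else {
    df <- do.call(rbind, lapply(runs, function(r) {
      d <- as.data.frame(r)
      d$tag <- tag %||% attr(r, "tag") %||% "run"
      d
    }))
  }
  if (!is.null(tag)) df$tag <- tag
  df$topic <- as.character(df$topic)
  df$doc_id <- as.character(df$doc_id)
  df
}

#' Read a TREC run file
#'
#' @param path Path to a six-column TREC run file.
#' @return A `data.frame` with columns `topic`, `doc_id`, `rank`, `score`,
#'   `tag`, ordered by topic and rank.
#' @export
read_run <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("topic", "q0", "doc_id", "rank", "score", "tag"),
                          colClasses = c("character", "character", "character",
                                         "integer", "numeric", "character"))
  df <- df[order(df$topic, df$rank), c("topic", "doc_id", "rank", "score", "tag")]
  rownames(df) <- NULL
  for (tp in split(df, df$topic)) {
    if (!identical(tp$rank, seq_len(nrow(tp))))
      stop("non-contiguous ranks for topic ", tp$topic[[1L]], " in ", path)
    if (is.unsorted(rev(tp$score))) stop("scores increase within topic ",
                                         tp$topic[[1L]], " in ", path)
  }
  df
}

#' Construct a qrels object
#'
#' Graded relevance judgments per topic, with optional sampling metadata for
#' the inferred measures. Judged documents carry a grade in \{0, 1, 2\};
#' documents that are members of the judgment pool but were not sampled are
#' recorded with grade `NA`. Every pool document has a stratum label, and each
#' topic/stratum sampling rate is the sampled fraction of that stratum's pool.
#'
#' @param df A `data.frame` with columns `topic`, `doc_id`, `grade` (0/1/2, or
#'   `NA`/-1 for pooled-but-unsampled) and optionally `stratum`.
#' @return An object of class `ds_qrels`: per topic, `judgments` (named
#'   grades), `pool` (doc -> stratum) and `rates` (stratum -> sampling rate).
#' @export
qrels <- function(df) {
  stopifnot(all(c("topic", "doc_id", "grade") %in% names(df)))
  df$topic <- as.character(df$topic)
  df$doc_id <- as.character(df$doc_id)
  df$grade <- as.numeric(df$grade)
  df$grade[!is.na(df$grade) & df$grade < 0] <- NA
  if (is.null(df$stratum)) df$stratum <- "all"
  bad <- !is.na(df$grade) & !df$grade %in% c(0, 1, 2)
  if (any(bad)) stop("grades must be 0/1/2 (or -1/NA for unsampled), got: ",
                     paste(unique(df$grade[bad]), collapse = ", "))
  topics <- lapply(split(df, df$topic), function(tp) {
    if (anyDuplicated(tp$doc_id)) stop("document judged more than once for topic ",
                                       tp$topic[[1L]])
    judged <- tp[!is.na(tp$grade), ]
    pool <- stats::setNames(as.character(tp$stratum), tp$doc_id)
    rates <- vapply(split(tp, tp$stratum), function(s) mean(!is.na(s$grade)), 0)
    list(judgments = stats::setNames(judged$grade, judged$doc_id),
         pool = pool, rates = rates)
  })
  structure(topics, class = "ds_qrels")
}

#' @export
print.ds_qrels <- function(x, ...) {
  nj <- sum(vapply(x, function(t) length(t$judgments), 0L))
  np <- sum(vapply(x, function(t) length(t$pool), 0L))
  cat("<ds_qrels> ", length(x), " topics, ", nj, " judgments, pool ", np, "\n", sep = "")
  invisible(x)
}

#' Read a qrels file
#'
#' Accepts the plain dialect `topic 0 doc_id grade` and the sampled dialect
#' with a fifth stratum column, in which pooled-but-unsampled documents carry
#' grade -1.
#'
#' @param path File path.
#' @return A `ds_qrels`.
#' @export
read_qrels <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L, warn = FALSE)), "\\s+")[[1L]]
  ncol <- length(first)
  if (!ncol %in% c(4L, 5L)) stop("qrels file must have 4 or 5 columns: ", path)
  cn <- c("topic", "iter", "doc_id", "grade", if (ncol == 5L) "stratum")
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = cn)
  df$iter <- NULL
  qrels(df)
}

#' Write a qrels object
#'
#' Writes the 5-column sampled dialect when any topic carries sampling
#' metadata (a stratum other than `"all"` or an unsampled pool document),
#' otherwise the plain 4-column dialect.
#'
#' @param q A `ds_qrels`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qrels <- function(q, path) {
  rows <- lapply(names(q), function(topic) {
    tp <- q[[topic]]
    grade <- ifelse(names(tp$pool) %in% names(tp$judgments),
                    tp$judgments[names(tp$pool)], -1)
    data.frame(topic = topic, iter = 0L, doc_id = names(tp$pool),
               grade = as.integer(grade), stratum = unname(tp$pool),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sampled <- any(df$grade < 0) || any(df$stratum != "all")
  if (!sampled) df$stratum <- NULL
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

# grade of doc for topic entry (0 when unjudged), vectorized over docs
qrels_grades <- function(tp, docs) {
  g <- tp$judgments[docs]
  g[is.na(g)] <- 0
  unname(g)
}
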