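# End-to-end orchestration: index -> query generation -> cascade retrieval ->
# re-ranking -> evaluation, plus the 2^3 feature-ablation harness over the
# three retrieval features (additional fields, standard fields, query
# expansion).

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (a `ds_benchmark`'s components) or file
#' paths in the formats [write_benchmark()] emits; paths are loaded lazily by
#' [run_pipeline()]. The three feature flags mirror the retrieval ablation:
#' include `additional.*` fields in the index, restrict indexing to the
#' standard fields, expand query concepts with the dictionary.
#'
#' @param corpus A `ds_corpus` or path to corpus JSON.
#' @param questions A data.frame (`topic_id`, `question`) or path to a TSV.
#' @param dictionary A `ds_dictionary` or path.
#' @param qrels A `ds_qrels` or path, or `NULL` to skip evaluation.
#' @param additional Additional-info list or path, or `NULL`.
#' @param surrogates Named list topic -> character vector, or a directory of
#'   fixture files (required only for method `"sqem"`).
#' @param schema A `ds_schema`, or `NULL` for all-fields indexing; its
#'   standard/additional switches are overridden by the feature flags.
#' @param additional_fields,standard_fields,query_expansion Feature flags.
#' @param methods Run methods: subset of `c("none", "psd-allwords",
#'   "psd-keywords", "sqem", "ensemble")`. `"none"` is the stage-1 cascade
#'   order; `"ensemble"` fuses psd-allwords and psd-keywords.
#' @param cap Stage-1 result cap per topic.
#' @param params A [psd_params()].
#' @param sqem_k Surrogate documents concatenated by SQEM.
#' @param out_dir If non-`NULL`, TREC run files and a metrics table are
#'   written there.
#' @param quiet Suppress stage messages.
#' @return A list of class `ds_pipeline_config`.
#' @export
pipeline_config <- function(corpus, questions, dictionary, qrels = NULL,
                            additional = NULL, surrogates = NULL, schema = NULL,
                            additional_fields = TRUE, standard_fields = TRUE,
                            query_expansion = TRUE,
                            methods = c("none", "psd-allwords"),
                            cap = 5000L, params = psd_params(), sqem_k = 10L,
                            out_dir = NULL, quiet = FALSE) {
  methods <- match.arg(methods,
                       c("none", "psd-allwords", "psd-keywords", "sqem", "ensemble"),
                       several.ok = TRUE)
  structure(list(corpus = corpus, questions = questions, dictionary = dictionary,
                 qrels = qrels, additional = additional, surrogates = surrogates,
                 schema = schema,
                 additional_fields = isTRUE(additional_fields),
                 standard_fields = isTRUE(standard_fields),
                 query_expansion = isTRUE(query_expansion),
                 methods = methods, cap = as.integer(cap), params = params,
                 sqem_k = as.integer(sqem_k), out_dir = out_dir,
                 quiet = isTRUE(quiet)),
            class = "ds_pipeline_config")
}

load_pipeline_inputs <- function(config) {
  cfg <- config
  if (is.character(cfg$corpus)) cfg$corpus <- read_corpus(cfg$corpus)
  if (is.character(cfg$additional)) cfg$additional <- read_additional_info(cfg$additional)
  if (is.character(cfg$questions)) {
    cfg$questions <- utils::read.table(cfg$questions, sep = "\t", header = FALSE,
                                       stringsAsFactors = FALSE,
                                       col.names = c("topic_id", "question"),
                                       quote = "")
  }
  if (is.character(cfg$dictionary)) cfg$dictionary <- read_dictionary(cfg$dictionary)
  if (is.character(cfg$qrels)) cfg$qrels <- read_qrels(cfg$qrels)
  cfg
}

pipeline_stage <- function(quiet, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.1fs", stage, proc.time()[["elapsed"]] - t0))
  out
}

surrogate_provider_from <- function(surrogates) {
  if (is.null(surrogates)) stop("method 'sqem' needs surrogates")
  if (is.character(surrogates) && length(surrogates) == 1L)
    return(fixture_surrogate_provider(surrogates))
  function(topic_id, question = NULL) {
    docs <- surrogates[[topic_id]]
    if (is.null(docs)) character() else docs
  }
}

#' Run the retrieval pipeline end to end
#'
#' Builds the index under the configured feature flags, generates one
#' Boolean concept query per question, retrieves candidates with the
#' minimum-match cascade, applies the configured re-ranking methods, and (if
#' qrels are available) scores every method with the full metric set.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `ds_pipeline_result`: `runs` (method -> list of
#'   `ds_ranked_list` per topic), `metrics` (method x metric means, or `NULL`),
#'   `per_topic`, `index` and the effective `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_inputs(config)
  corpus <- cfg$corpus
  if (!is.null(cfg$additional))
    corpus <- pipeline_stage(cfg$quiet, "merge-additional",
                             merge_additional_info(corpus, cfg$additional, quiet = TRUE))
  schema <- cfg$schema %||% field_schema(standard_fields = NULL)
  schema$use_standard_fields <- cfg$standard_fields && !is.null(schema$standard_fields)
  schema$use_additional_fields <- cfg$additional_fields
  index <- pipeline_stage(cfg$quiet, "index", build_index(corpus, schema))

  queries <- pipeline_stage(cfg$quiet, "query-generation",
    lapply(seq_len(nrow(cfg$questions)), function(i)
      generate_query(cfg$questions$topic_id[[i]], cfg$questions$question[[i]],
                     dictionary = cfg$dictionary, expand = cfg$query_expansion)))

  stage1 <- pipeline_stage(cfg$quiet, "retrieve",
    lapply(queries, function(q) retrieve_cascade(index, q, cap = cfg$cap)))
  names(stage1) <- vapply(queries, `[[`, "", "topic_id")

  runs <- list()
  for (method in cfg$methods) {
    if (method == "ensemble") next
    runs[[method]] <- pipeline_stage(cfg$quiet, method, {
      out <- lapply(seq_along(stage1), function(i) {
        cand <- stage1[[i]]
        topic <- names(stage1)[[i]]
        question <- cfg$questions$question[[match(topic, cfg$questions$topic_id)]]
        if (nrow(cand) == 0L) return(cand)
        switch(method,
          "none" = cand,
          "psd-allwords" = rerank_psd_allwords(question, cand, index, cfg$params),
          "psd-keywords" = rerank_psd_keywords(
            question, cand, index,
            recognizer = dictionary_recognizer(cfg$dictionary), params = cfg$params),
          "sqem" = rerank_sqem(question, cand, index,
                               provider = surrogate_provider_from(cfg$surrogates),
                               topic_id = topic, k = cfg$sqem_k, params = cfg$params))
      })
      names(out) <- names(stage1)
      out
    })
  }
  if ("ensemble" %in% cfg$methods) {
    parts <- intersect(c("psd-allwords", "psd-keywords"), names(runs))
    if (length(parts) < 2L)
      stop("pipeline stage 'ensemble' failed: needs psd-allwords and psd-keywords runs")
    runs[["ensemble"]] <- pipeline_stage(cfg$quiet, "ensemble", {
      out <- lapply(names(stage1), function(topic) {
        inputs <- lapply(parts, function(m) runs[[m]][[topic]])
        inputs <- inputs[vapply(inputs, nrow, 0L) > 0L]
        if (length(inputs) < 2L) return(runs[[parts[[1L]]]][[topic]])
        ensemble(inputs)
      })
      names(out) <- names(stage1)
      out
    })
  }

  metrics <- NULL; per_topic <- NULL
  if (!is.null(cfg$qrels)) {
    ev <- pipeline_stage(cfg$quiet, "evaluate",
      lapply(runs, function(rs) evaluate_run(rs, cfg$qrels)))
    metrics <- do.call(rbind, lapply(ev, `[[`, "mean"))
    per_topic <- lapply(ev, `[[`, "per_topic")
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (method in names(runs))
      write_run(runs[[method]], file.path(cfg$out_dir, paste0(method, ".run")),
                tag = method)
    if (!is.null(metrics))
      utils::write.table(data.frame(method = rownames(metrics), metrics),
                         file.path(cfg$out_dir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(runs = runs, metrics = metrics, per_topic = per_topic,
                 index = index, config = cfg),
            class = "ds_pipeline_result")
}

#' @export
print.ds_pipeline_result <- function(x, ...) {
  cat("<ds_pipeline_result> methods: ", paste(names(x$runs), collapse = ", "), "\n", sep = "")
  if (!is.null(x$metrics)) print(round(x$metrics, 4))
  invisible(x)
}

#' Feature-ablation experiment
#'
#' Runs the stage-1 pipeline for all eight combinations of the three
#' retrieval features — additional fields (A), standard fields (S), query
#' expansion (E) — in the canonical row order YYY, NYY, YNY, YYN, YNN, NYN,
#' NNY, NNN, and tabulates the evaluation metrics per row.
#'
#' @param config A [pipeline_config()] with qrels; its flags are overridden
#'   row by row and its methods are fixed to `"none"`.
#' @return A data.frame with columns `additional_fields`, `standard_fields`,
#'   `query_expansion` (Y/N) followed by the metric means.
#' @export
run_ablation <- function(config) {
  combos <- rbind(
    c("Y", "Y", "Y"), c("N", "Y", "Y"), c("Y", "N", "Y"), c("Y", "Y", "N"),
    c("Y", "N", "N"), c("N", "Y", "N"), c("N", "N", "Y"), c("N", "N", "N"))
  cfg <- load_pipeline_inputs(config)
  cfg$methods <- "none"
  cfg$out_dir <- NULL
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cfg$additional_fields <- combos[i, 1L] == "Y"
    cfg$standard_fields <- combos[i, 2L] == "Y"
    cfg$query_expansion <- combos[i, 3L] == "Y"
    res <- run_pipeline(cfg)
    data.frame(additional_fields = combos[i, 1L], standard_fields = combos[i, 2L],
               query_expansion = combos[i, 3L],
               as.list(res$metrics["none", ]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
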