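# Seeded synthetic benchmark: corpora with Zipf background text and planted
# relevant documents, questions, an expansion dictionary, graded qrels and
# surrogate-document fixtures, so that indexing, query generation, the
# cascade, the re-rankers and the evaluators are all exercisable offline with
# known structure. Relevant documents contain all topic concepts, partially
# relevant documents a strict subset, all other documents none.

#' Synthetic benchmark configuration
#'
#' Defaults define the package's reference benchmark: 2000 documents, 10
#' topics with 3 two-token concepts each, 10 relevant and 5 partially
#' relevant documents per topic. A fifth of the relevant documents express
#' every concept only through dictionary synonyms (so retrieval without
#' expansion must miss them), and 40 percent express two of their three
#' concepts non-contiguously (tokens present but the phrase broken, emulating
#' unnormalized concept mentions), which Boolean phrase tiering under-ranks
#' and unigram re-scoring can recover.
#'
#' @param seed RNG seed; the whole benchmark is reproducible from it.
#' @param n_docs Corpus size.
#' @param vocab_size Background vocabulary size.
#' @param zipf_exponent Exponent of the Zipf background term distribution.
#' @param n_topics Number of topics.
#' @param n_concepts Concepts per topic.
#' @param n_relevant,n_partial Planted grade-2 / grade-1 documents per topic.
#' @param boost Concept-term frequency multiplier in planted documents
#'   (number of times each planted representation is inserted; must be > 1).
#' @param synonym_only_frac Fraction of relevant documents using only synonym
#'   representations.
#' @param scattered_frac Fraction of relevant documents whose non-anchor
#'   concepts appear non-contiguously.
#' @param additional_frac Fraction of background documents that carry
#'   additional-information records; relevant documents flagged as
#'   additional-carriers keep their third concept only in
#'   `additional.summary`.
#' @param n_judged_nonrel Judged nonrelevant (grade 0) documents per topic.
#' @param doc_len_mean Mean background token count per document.
#' @return A list of class `ds_synth_config`.
#' @export
synthetic_config <- function(seed = 1234L, n_docs = 2000L, vocab_size = 2000L,
                             zipf_exponent = 1.1, n_topics = 10L,
                             n_concepts = 3L, n_relevant = 10L, n_partial = 5L,
                             boost = 4L, synonym_only_frac = 0.2,
                             scattered_frac = 0.4, additional_frac = 0.3,
                             n_judged_nonrel = 30L, doc_len_mean = 80) {
  cfg <- list(seed = as.integer(seed), n_docs = as.integer(n_docs),
              vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
              n_topics = as.integer(n_topics), n_concepts = as.integer(n_concepts),
              n_relevant = as.integer(n_relevant), n_partial = as.integer(n_partial),
              boost = as.integer(boost), synonym_only_frac = synonym_only_frac,
              scattered_frac = scattered_frac, additional_frac = additional_frac,
              n_judged_nonrel = as.integer(n_judged_nonrel),
              doc_len_mean = doc_len_mean)
  planted <- cfg$n_topics * (cfg$n_relevant + cfg$n_partial)
  if (planted > cfg$n_docs)
    stop("infeasible config: ", planted, " planted docs exceed n_docs = ", cfg$n_docs)
  if (cfg$boost <= 1L) stop("boost must be > 1")
  if (cfg$n_concepts < 2L) stop("need >= 2 concepts per topic (partials are strict subsets)")
  for (fr in c(cfg$synonym_only_frac, cfg$scattered_frac, cfg$additional_frac))
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]")
  class(cfg) <- "ds_synth_config"
  cfg
}

# Deterministic pseudo-biomedical background vocabulary (no RNG, no digits,
# disjoint from the digit-bearing concept tokens, no packaged stopwords).
synth_vocabulary <- function(n) {
  syl <- c("gen", "prot", "cell", "neur", "card", "hepat", "immun", "cyt",
           "fibr", "lip", "glyc", "path", "plasm", "derm", "oste", "vasc",
           "ren", "pulm", "gastr", "myel")
  tail <- c("ase", "ine", "oma", "itis", "osis", "emia", "ide", "ogen",
            "actin", "ol")
  words <- character(n)
  k <- 1L
  for (i in seq_along(syl)) for (j in seq_along(syl)) for (t in seq_along(tail)) {
    if (k > n) break
    words[[k]] <- paste0(syl[[i]], syl[[j]], tail[[t]])
    k <- k + 1L
  }
  if (k <= n) stop("vocabulary request too large: ", n)
  stop_all <- unique(c(load_stopwords("pubmed"), load_stopwords("english"),
                       load_stopwords("question")))
  words <- setdiff(words, stop_all)
  words[seq_len(min(n, length(words)))]
}

concept_token <- function(topic, con, k) sprintf("%s%02d%02d%s",
  c("tgf", "smad", "wnt", "notch", "stat")[(con - 1L) %% 5L + 1L], topic, con,
  letters[[k]])

# Per-topic concept book: surface tokens, synonyms, dictionary entries.
synth_concepts <- function(cfg) {
  lapply(seq_len(cfg$n_topics), function(t) {
    lapply(seq_len(cfg$n_concepts), function(j) {
      surface <- c(concept_token(t, j, 1L), concept_token(t, j, 2L))
      syn1 <- c(sprintf("alias%02d%02da", t, j), sprintf("alias%02d%02db", t, j))
      syn2 <- c(sprintf("longform%02d%02d", t, j), sprintf("variant%02d%02d", t, j))
      list(surface = paste(surface, collapse = " "),
           surface_tokens = surface,
           synonyms = list(syn1, syn2))
    })
  })
}

# Insert each phrase in `phrases` (list of token vectors) `times` times at
# random positions, keeping the phrase tokens contiguous.
insert_intact <- function(bg, phrases, times) {
  units <- as.list(bg)
  for (ph in phrases) for (i in seq_len(times)) {
    pos <- sample.int(length(units) + 1L, 1L)
    units <- append(units, list(ph), after = pos - 1L)
  }
  unlist(units)
}

# Insert the tokens of each phrase `times` times, one token per distinct gap
# between background tokens, so no two inserted tokens are ever adjacent
# (background words are never stopwords, so gaps survive analysis).
insert_scattered <- function(bg, phrases, times) {
  toks <- unlist(lapply(phrases, function(ph) rep(ph, times)))
  n_gaps <- length(bg) - 1L
  if (length(toks) > n_gaps)
    stop("document too short to scatter ", length(toks), " tokens")
  gaps <- sort(sample.int(n_gaps, length(toks)))
  toks <- sample(toks)                       # shuffle which token lands where
  out <- character(0)
  prev <- 1L
  for (i in seq_along(gaps)) {
    out <- c(out, bg[prev:gaps[[i]]], toks[[i]])
    prev <- gaps[[i]] + 1L
  }
  c(out, bg[prev:length(bg)])
}

synth_background <- function(vocab, probs, len) {
  sample(vocab, size = len, replace = TRUE, prob = probs)
}

#' Generate the synthetic benchmark
#'
#' Builds, fully reproducibly from `config$seed`: a corpus of metadata
#' records, additional-information records, one free-text question per topic,
#' an expansion dictionary covering every planted concept, fully judged
#' graded qrels (grade 2 for relevant, 1 for partially relevant, 0 for a
#' sample of judged nonrelevant documents) and per-topic surrogate-document
#' fixtures (concatenations of relevant-document texts).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `ds_benchmark` with elements `corpus`,
#'   `additional`, `questions`, `dictionary`, `qrels`, `surrogates`, `schema`
#'   and `config`.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  vocab <- synth_vocabulary(cfg$vocab_size)
  probs <- (1 / seq_along(vocab)^cfg$zipf_exponent)
  probs <- probs / sum(probs)
  concepts <- synth_concepts(cfg)
  repos <- c("GEO", "ArrayExpress", "PDB", "ClinicalTrials")

  n_planted <- cfg$n_topics * (cfg$n_relevant + cfg$n_partial)
  doc_ids <- sprintf("DS%05d", seq_len(cfg$n_docs))
  planted_ids <- sample(doc_ids, n_planted)           # spread planted docs around
  rest_ids <- setdiff(doc_ids, planted_ids)

  # role bookkeeping per topic
  qrels_rows <- list()
  questions <- data.frame(topic_id = character(), question = character(),
                          stringsAsFactors = FALSE)
  surrogates <- list()
  records <- vector("list", cfg$n_docs)
  names(records) <- doc_ids
  additional <- list()

  make_background <- function(min_len = 30L) {
    len <- max(min_len, stats::rpois(1L, cfg$doc_len_mean))
    synth_background(vocab, probs, len)
  }
  base_fields <- function(desc_tokens, repo, extra_title = character()) {
    title <- c(extra_title, synth_background(vocab, probs, 5L))
    list(
      "metadata.title" = paste(title, collapse = " "),
      "metadata.description" = paste(desc_tokens, collapse = " "),
      "metadata.keywords" = paste(synth_background(vocab, probs, 4L), collapse = " "),
      "metadata.dataType" = "expression profiling",
      "metadata.releaseDate" = sprintf("2016-%02d-%02d", sample.int(12L, 1L), sample.int(28L, 1L)),
      "metadata.misc.note" = paste(synth_background(vocab, probs, 10L), collapse = " ")
    )
  }

  pid <- 1L
  for (t in seq_len(cfg$n_topics)) {
    topic_id <- sprintf("T%02d", t)
    cons <- concepts[[t]]
    n_syn <- ceiling(cfg$synonym_only_frac * cfg$n_relevant)
    n_scatter_half <- ceiling(cfg$scattered_frac * cfg$n_relevant / 2)
    rel_texts <- character(cfg$n_relevant)

    for (j in seq_len(cfg$n_relevant)) {
      id <- planted_ids[[pid]]; pid <- pid + 1L
      syn_only <- j <= n_syn
      within <- if (syn_only) j else j - n_syn
      scattered <- within <= n_scatter_half
      carrier <- !scattered && cfg$additional_frac > 0 &&
        within == (if (syn_only) n_syn else cfg$n_relevant - n_syn)
      rep_tokens <- lapply(seq_len(cfg$n_concepts), function(cj) {
        if (syn_only) {
          syn <- cons[[cj]]$synonyms[[(j + cj) %% 2L + 1L]]
          if (is.character(syn)) unlist(strsplit(paste(syn, collapse = " "), " ")) else syn
        } else cons[[cj]]$surface_tokens
      })
      bg <- make_background(min_len = 60L)
      anchor <- rep_tokens[1L]
      others <- rep_tokens[-1L]
      if (scattered) {
        # scatter first, then insert the intact anchor phrase, so scattering
        # can never split the anchor and the anchor cannot join two
        # scattered tokens (its insertion only pushes them further apart)
        desc <- insert_scattered(bg, others, cfg$boost)
        desc <- insert_intact(desc, anchor, cfg$boost)
        add_text <- NULL
      } else if (carrier) {
        desc <- insert_intact(bg, c(anchor, others[-length(others)]), cfg$boost)
        add_text <- paste(insert_intact(synth_background(vocab, probs, 15L),
                                        others[length(others)], cfg$boost),
                          collapse = " ")
      } else {
        desc <- insert_intact(bg, rep_tokens, cfg$boost)
        add_text <- NULL
      }
      repo <- repos[[(pid %% length(repos)) + 1L]]
      records[[id]] <- metadata_record(id, base_fields(desc, repo), repository = repo)
      if (!is.null(add_text)) {
        additional[[length(additional) + 1L]] <-
          list(doc_id = id, summary = add_text, title = "", overall_design = "")
      }
      rel_texts[[j]] <- paste(desc, collapse = " ")
      qrels_rows[[length(qrels_rows) + 1L]] <-
        data.frame(topic = topic_id, doc_id = id, grade = 2, stringsAsFactors = FALSE)
    }

    for (j in seq_len(cfg$n_partial)) {
      id <- planted_ids[[pid]]; pid <- pid + 1L
      subset_cons <- seq_len(cfg$n_concepts - 1L)       # strict subset: all but last
      rep_tokens <- lapply(subset_cons, function(cj) cons[[cj]]$surface_tokens)
      desc <- insert_intact(make_background(min_len = 60L), rep_tokens, cfg$boost)
      repo <- repos[[(pid %% length(repos)) + 1L]]
      records[[id]] <- metadata_record(id, base_fields(desc, repo), repository = repo)
      qrels_rows[[length(qrels_rows) + 1L]] <-
        data.frame(topic = topic_id, doc_id = id, grade = 1, stringsAsFactors = FALSE)
    }

    surfaces <- vapply(cons, `[[`, "", "surface")
    questions <- rbind(questions, data.frame(
      topic_id = topic_id,
      question = paste("Find all datasets related to",
                       paste(surfaces, collapse = " "),
                       "studies across all databases"),
      stringsAsFactors = FALSE))
    surrogates[[topic_id]] <- utils::head(rel_texts, 10L)
  }

  for (id in rest_ids) {
    repo <- repos[[(match(id, doc_ids) %% length(repos)) + 1L]]
    records[[id]] <- metadata_record(id, base_fields(make_background(), repo),
                                     repository = repo)
    if (stats::runif(1L) < cfg$additional_frac) {
      additional[[length(additional) + 1L]] <-
        list(doc_id = id,
             summary = paste(synth_background(vocab, probs, 15L), collapse = " "),
             title = "", overall_design = "")
    }
  }

  # judged nonrelevant background docs per topic
  for (t in seq_len(cfg$n_topics)) {
    topic_id <- sprintf("T%02d", t)
    zeros <- sample(rest_ids, min(cfg$n_judged_nonrel, length(rest_ids)))
    qrels_rows[[length(qrels_rows) + 1L]] <-
      data.frame(topic = topic_id, doc_id = zeros, grade = 0, stringsAsFactors = FALSE)
  }

  dict_entries <- list()
  for (t in seq_len(cfg$n_topics)) for (cj in seq_len(cfg$n_concepts)) {
    con <- concepts[[t]][[cj]]
    dict_entries[[normalize_phrase(con$surface)]] <-
      vapply(con$synonyms, function(s) paste(s, collapse = " "), "")
  }
  dictionary <- as_dictionary(dict_entries)

  structure(list(
    corpus = as_corpus(records),
    additional = additional,
    questions = questions,
    dictionary = dictionary,
    qrels = qrels(do.call(rbind, qrels_rows)),
    surrogates = surrogates,
    schema = field_schema(
      standard_fields = c("metadata.title", "metadata.description",
                          "metadata.keywords", "metadata.dataType")),
    config = cfg
  ), class = "ds_benchmark")
}

#' @export
print.ds_benchmark <- function(x, ...) {
  cat("<ds_benchmark> ", length(x$corpus), " docs, ", nrow(x$questions),
      " topics, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Build a dictionary from in-memory entries
#'
#' @param entries Named list: normalized phrase -> character vector of
#'   expansions.
#' @return A `ds_dictionary`.
#' @export
as_dictionary <- function(entries) {
  keys <- normalize_phrase(names(entries))
  dict <- stats::setNames(lapply(entries, function(e) unique(as.character(e))), keys)
  attr(dict, "phrases") <- stats::setNames(names(entries), keys)
  class(dict) <- "ds_dictionary"
  dict
}

#' Write a dictionary as a TSV resource
#' @param dictionary A `ds_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  phrases <- attr(dictionary, "phrases")
  lines <- vapply(names(dictionary), function(k)
    paste0(phrases[[k]], "\t", paste(dictionary[[k]], collapse = "|")), "")
  writeLines(c("# datasearch expansion dictionary", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Write a benchmark to disk in the pipeline's file formats
#'
#' Emits `corpus.jsonl`, `additional.jsonl`, `questions.tsv` (topic_id TAB
#' question), `dictionary.tsv`, `qrels.txt` and a `surrogates/` directory with
#' one fixture file per topic.
#'
#' @param bench A `ds_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(bench$corpus, file.path(dir, "corpus.jsonl"))
  writeLines(vapply(bench$additional, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), ""),
    file.path(dir, "additional.jsonl"), useBytes = TRUE)
  utils::write.table(bench$questions, file.path(dir, "questions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_dictionary(bench$dictionary, file.path(dir, "dictionary.tsv"))
  write_qrels(bench$qrels, file.path(dir, "qrels.txt"))
  sdir <- file.path(dir, "surrogates")
  dir.create(sdir, showWarnings = FALSE)
  for (topic in names(bench$surrogates)) {
    writeLines(paste(bench$surrogates[[topic]], collapse = "\n\n"),
               file.path(sdir, paste0(topic, ".txt")), useBytes = TRUE)
  }
  invisible(dir)
}

#' Subsample judgments for inferred-measure validation
#'
#' Draws a without-replacement sample of each topic's judged documents and
#' records sampling metadata (pool membership, stratum labels, implied
#' rates). `strata = "uniform"` samples one stratum; `strata = "two"` splits
#' each topic's pool into two equal strata (by document identifier order)
#' sampled independently at the same rate.
#'
#' @param q A fully judged `ds_qrels`.
#' @param rate Sampling rate in (0, 1].
#' @param seed RNG seed.
#' @param strata `"uniform"` or `"two"`.
#' @return A `ds_qrels` with sampling metadata.
#' @export
subsample_qrels <- function(q, rate, seed = 1L, strata = c("uniform", "two")) {
  if (!is.numeric(rate) || rate <= 0 || rate > 1)
    stop("rate must lie in (0, 1], got ", rate)
  strata <- match.arg(strata)
  set.seed(seed)
  rows <- list()
  for (topic in names(q)) {
    tp <- q[[topic]]
    if (length(tp$judgments) < length(tp$pool))
      stop("subsample_qrels expects fully judged input qrels")
    docs <- sort(names(tp$judgments))
    slab <- if (strata == "uniform") rep("s1", length(docs)) else
      rep(c("s1", "s2"), length.out = length(docs))[rank(docs)]
    keep <- character()
    for (s in unique(slab)) {
      ds <- docs[slab == s]
      keep <- c(keep, sample(ds, round(rate * length(ds))))
    }
    grade <- ifelse(docs %in% keep, tp$judgments[docs], NA)
    rows[[topic]] <- data.frame(topic = topic, doc_id = docs, grade = grade,
                                stratum = slab, stringsAsFactors = FALSE)
  }
  qrels(do.call(rbind, rows))
}
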