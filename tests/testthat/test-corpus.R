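test_that("read_corpus reads a directory of JSON documents and flattens nesting", {
  dir <- withr::local_tempdir()
  writeLines('{"id": "DS1", "metadata": {"description": "x"}}', file.path(dir, "a.json"))
  writeLines('{"id": "DS2", "metadata": {"title": "t", "tags": ["p53", "brca1"]}}',
             file.path(dir, "b.json"))
  writeLines('{"id": "DS3", "repository": "GEO", "metadata": {"description": "z"}}',
             file.path(dir, "c.json"))
  corpus <- read_corpus(dir)
  expect_s3_class(corpus, "ds_corpus")
  expect_length(corpus, 3L)
  expect_identical(unname(corpus[["DS1"]]$fields[["metadata.description"]]), "x")
  # scalar arrays join with a single space
  expect_identical(unname(corpus[["DS2"]]$fields[["metadata.tags"]]), "p53 brca1")
  expect_identical(corpus[["DS3"]]$repository, "GEO")
})

test_that("duplicate doc_ids are a hard error naming both files", {
  dir <- withr::local_tempdir()
  writeLines('{"id": "DS1", "metadata": {"description": "x"}}', file.path(dir, "a.json"))
  writeLines('{"id": "DS1", "metadata": {"description": "y"}}', file.path(dir, "b.json"))
  expect_error(read_corpus(dir), "DS1.*b\\.json.*a\\.json")
})

test_that("malformed JSON files are skipped with a warning, processing continues", {
  dir <- withr::local_tempdir()
  writeLines('{"id": "DS1", "metadata": {"description": "x"}}', file.path(dir, "a.json"))
  writeLines('{"id": "DS2", not json at all', file.path(dir, "bad.json"))
  expect_warning(corpus <- read_corpus(dir), "bad\\.json")
  expect_length(corpus, 1L)
})

test_that("corpus round-trips through write_corpus field-identically", {
  dir <- withr::local_tempdir()
  writeLines('{"id": "DS1", "metadata": {"description": "alpha beta", "date": "2016-01-01"}}',
             file.path(dir, "a.json"))
  corpus <- read_corpus(dir)
  out <- file.path(dir, "roundtrip.jsonl")
  write_corpus(corpus, out)
  corpus2 <- read_corpus(out)
  expect_identical(names(corpus2), names(corpus))
  for (id in names(corpus)) {
    expect_identical(corpus2[[id]]$fields, corpus[[id]]$fields)
    expect_identical(corpus2[[id]]$groups, corpus[[id]]$groups)
    expect_identical(corpus2[[id]]$repository, corpus[[id]]$repository)
  }
})

test_that("field groups default to string, with date-like paths as other and configured exact", {
  rec <- metadata_record("DS1",
    c("metadata.description" = "d", "metadata.releaseDate" = "2016-01-01",
      "metadata.mesh" = "Neoplasms"),
    exact_paths = "metadata.mesh")
  expect_identical(unname(rec$groups[c("metadata.description", "metadata.releaseDate",
                                       "metadata.mesh")]),
                   c("string", "other", "exact"))
})

test_that("merge_additional_info adds namespaced fields, never overwrites, and is idempotent", {
  corpus <- tiny_corpus(c(DS1 = "alpha", DS2 = "beta"))
  extra <- list(list(doc_id = "DS1", summary = "s", title = "ti", overall_design = ""))
  merged <- merge_additional_info(corpus, extra, quiet = TRUE)
  expect_identical(unname(merged[["DS1"]]$fields[["additional.summary"]]), "s")
  expect_identical(unname(merged[["DS1"]]$fields[["additional.title"]]), "ti")
  expect_false("additional.overall_design" %in% names(merged[["DS1"]]$fields))
  expect_identical(unname(merged[["DS1"]]$groups[["additional.summary"]]), "string")
  # idempotent: applying the same extras twice equals applying once
  twice <- merge_additional_info(merged, extra, quiet = TRUE)
  expect_identical(twice, merged)
  # record count is preserved and untouched records are unchanged
  expect_length(merged, 2L)
  expect_identical(merged[["DS2"]], corpus[["DS2"]])
})

test_that("unmatched extras leave the corpus unchanged and are counted", {
  corpus <- tiny_corpus(c(DS1 = "alpha"))
  extra <- list(list(doc_id = "DS9", summary = "s", title = "", overall_design = ""))
  expect_message(merged <- merge_additional_info(corpus, extra),
                 "1 additional-info entry matched no record")
  expect_identical(merged, corpus)
})

test_that("a bulk merge touches exactly the matched records", {
  ids <- sprintf("DS%03d", 1:200)
  corpus <- tiny_corpus(stats::setNames(paste("text", ids), ids))
  hit <- sample(ids, 100)
  extra <- lapply(hit, function(id)
    list(doc_id = id, summary = paste("summary for", id), title = "", overall_design = ""))
  merged <- merge_additional_info(corpus, extra, quiet = TRUE)
  gained <- vapply(merged, function(r) "additional.summary" %in% names(r$fields), TRUE)
  expect_identical(sort(names(merged)[gained]), sort(hit))
  expect_length(merged, 200L)
})

test_that("schema scoping selects standard and additional fields per the flags", {
  rec <- metadata_record("DS1",
    c("metadata.title" = "t", "metadata.description" = "d",
      "metadata.misc" = "m", "additional.summary" = "s"))
  std <- c("metadata.title", "metadata.description")
  expect_setequal(
    fields_in_scope_for_test(rec, field_schema(std)),
    c(std, "additional.summary"))
  expect_setequal(
    fields_in_scope_for_test(rec, field_schema(std, use_additional_fields = FALSE)),
    std)
  expect_setequal(
    fields_in_scope_for_test(rec, field_schema(std, use_standard_fields = FALSE)),
    c("metadata.title", "metadata.description", "metadata.misc", "additional.summary"))
})

test_that("check_schema warns about standard fields absent from a repository", {
  corpus <- tiny_corpus(c(DS1 = "alpha"))
  schema <- field_schema(c("metadata.description", "metadata.nosuch"))
  expect_warning(check_schema(schema, corpus), "metadata\\.nosuch")
})
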