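Package: datasearch
Title: Biomedical Dataset Retrieval with Boolean Query Generation and
    Language-Model Re-Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for cross-repository biomedical dataset
    retrieval. Indexes DATS-like dataset metadata records into an inverted
    index, turns free-text user questions into nested Boolean concept queries
    with offline synonym expansion, retrieves candidates with a minimum-match
    cascade, and re-ranks them with a pseudo-sequential-dependence (PSD)
    Dirichlet-smoothed language model, a snippet-based query expansion method
    (SQEM) over surrogate documents, and a reciprocal-rank ensemble. Runs are
    scored against graded TREC-style judgments with Precision@10, NDCG@10 and
    the inferred measures infAP and infNDCG, including support for sampled
    judgment pools. A seeded synthetic-benchmark generator with planted
    relevant documents makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
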