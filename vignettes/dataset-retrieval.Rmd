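---
title: "Cross-repository dataset retrieval: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-repository dataset retrieval: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datasearch)
```

## The problem

Biomedical datasets are scattered across repositories (GEO, ArrayExpress, PDB,
ClinicalTrials, ...) whose harmonized metadata — short fielded descriptions in
a DATS-like structure — is all a search engine gets to see. A user types a
free-text question ("find data of all types related to TGF-beta signaling
pathway across all databases") and expects a ranked list of datasets.
`datasearch` implements a complete retrieve-then-re-rank pipeline for this
setting: metadata indexing, automatic Boolean query generation with synonym
expansion, a minimum-match cascade for candidate generation, language-model
re-ranking, rank fusion, and TREC-style evaluation with graded and sampled
judgments. Everything runs offline; a seeded generator builds corpora with
planted relevant documents so every stage is testable without external
services.

## Text analysis

One deterministic analyzer chain is used on both the index side and the query
side (using different chains is a classic source of silent term mismatch):

1. Unicode word tokenization (split on non-alphanumerics; interior
   apostrophes stay with their word),
2. trailing possessive (`'s`) stripping,
3. lowercasing,
4. ASCII folding (Latin diacritics transliterated, other non-ASCII dropped),
5. stopword removal (the packaged PubMed-style indexing list),
6. a light English stemmer.

The stemmer is deliberately conservative: a frozen table of plural rules
(`-ies → -y`, `-sses → -ss`, `-xes/-ches/-shes/-zes/-oes/-uses → drop -es`,
otherwise drop a final `-s`; words of three or fewer characters, `-ss`/`-us`/
`-is` endings and digit-bearing tokens are untouched). Freezing the table in
the package makes analysis reproducible across environments — stemming
behavior is part of the index format. Controlled-vocabulary phrases (MeSH
headings and entry terms) can be declared *protected*: their tokens bypass
the stemmer so "Neoplasms" is indexed verbatim. The stopword filter is
applied before stemming and also to protected tokens; protection only
shields a token from the stemmer.

## Indexing

`build_index()` analyzes every in-scope field and keeps, besides postings,
exactly the statistics the ranking models need: per-document term frequency
`tf` (summed over all in-scope fields — the document is scored as one bag of
words), collection frequency `cf`, document length $|D|$ and collection
length $|C|$, both counted over post-analysis tokens. Per-field token streams
are retained so multi-token representations can be matched by adjacency
within a single field (no cross-field phrases). Field groups control
indexing: `string` fields are analyzed text, `exact` fields are additionally
stored unanalyzed for whole-value matching, `other` fields (dates) are
skipped. A schema selects the per-repository "standard fields" and whether
the `additional.*` namespace (harvested Summary/Title/Overall-design texts)
is included; these are the switches the ablation harness flips.

## Query generation

Free-text questions are reduced to keywords by removing general-English
stopwords plus a short list of dataset-search boilerplate ("data",
"dataset", "find", "across", ...). The keywords are segmented greedily,
longest match first, against an offline expansion dictionary whose lookup is
case- and hyphen/space-insensitive ("TGF-beta" finds the entry "tgf beta");
out-of-dictionary words become singleton concepts. Each dictionary concept
carries its expansions, e.g.

```{r}
print(generate_query("T1",
  "find data of all types related to TGF-beta signaling pathway across all databases"))
```

A document *expresses* a concept when any representation (or the surface
form) occurs contiguously in one field, or equals an exact-field value. The
nested Boolean query requires at least `minimum_match` concepts; retrieval
relaxes this tier by tier from "all concepts" down to 1, ranking
higher-match tiers first and ordering within tiers by BM25
(`k1 = 1.2, b = 0.75`). BM25 is this package's choice for the within-tier
base score — the stage-1 engine's internal similarity is otherwise
unspecified — and the tier/score pair is flattened to the single sortable
real `matched_count + bm25/(1 + bm25)`, whose second summand lies in
`[0, 1)` so tiers can never interleave. Ties are broken by ascending
document identifier everywhere; the candidate list is truncated at 5000.
Greedy longest-match segmentation is this package's stand-in for PubMed-style
automatic term mapping, whose internals are not public.

## PSD re-ranking

Candidates are re-scored with a pseudo-sequential-dependence (PSD) model: a
sequential-dependence variant with the bigram components removed (unigrams
only) and a presence bonus. For query tokens $q_i$ and dataset $D$:

$$P = \sum_{q_i \in Q} f(q_i, D), \qquad
f(q_i, D) = \log\frac{\mathbb{1}(tf_{q_i,D} > 0)\,(tf_{q_i,D} + \delta) +
\mu\, cf_{q_i} / |C|}{|D| + \mu}$$

with defaults $\delta = 5$ and $\mu = 2500$. This is a Dirichlet-smoothed
query likelihood in which any term that occurs at all has $\delta$ added to
its frequency: *whether* a word occurs in the short metadata outweighs *how
often*. Numerical choices: the logarithm is natural (the base only scales
scores monotonically and cannot change a ranking; it matters only for score
comparability across runs); query tokens absent from the whole collection
(`cf = 0`) are skipped rather than made an error, since free-text questions
routinely contain words a metadata corpus lacks; a repeated query token
contributes once per occurrence; the question passes through the index
analyzer so stopword mass the index cannot match never enters $Q$.

Three inputs to the same scorer give the three re-rankers: the full question
(PSD-allwords); only the concept phrases a recognizer finds in the question,
deduplicated (PSD-keywords, with a dictionary-lookup recognizer standing
behind the same interface an external named-entity tool would use); or a
*surrogate document* — the concatenation of the top `k = 10` externally
retrieved texts for the question (SQEM), supplied by a pluggable provider
that in tests reads fixture files, so no live web search is ever needed. The
reciprocal-rank ensemble fuses two or more runs by the mean of `1/rank`
(0 for a list the document is absent from — the inputs in practice share one
candidate pool, so absence is an edge case that needs a rule, not a model).

## Evaluation

Runs are scored with five measures: P@10 counting partial relevance as
relevant or not (denominator fixed at 10), NDCG@10 with *linear* graded
gains (2/1/0, the convention of the NIST tools this format follows, not
exponential gains — configurable in principle, fixed here for
comparability), and the inferred measures for sampled judgment pools:

* **infAP** estimates average precision from a stratified random sample of
  the pool: for each sampled relevant document at rank $k$ the expected
  precision above $k$ is estimated per stratum from the pool composition and
  the within-sample relevance rate (with an $\varepsilon = 10^{-5}$ smoother
  for partially sampled strata), and contributions are inverse-rate weighted
  against the estimated total number of relevant documents.
* **infNDCG** estimates the full-list DCG by a Horvitz-Thompson sum — each
  sampled judged document contributes its discounted gain scaled by
  `1/rate` at its actual rank, which is unbiased under within-stratum
  uniform sampling — and divides by an ideal DCG built from inverse-rate
  estimates of the per-grade counts, allocating fractional document mass
  grade 2 first.

Both estimators drop the smoothing when a stratum is fully sampled, so at a
100% sampling rate they reduce *exactly* (to 1e-9) to AP and full-list NDCG.
The unbiasedness validation in the test suite subsamples a fully judged
400-document topic at 50% uniformly, 500 times, and checks that the mean
estimate falls within two standard errors of the exact value; the
two-stratum sampler is additionally exercised for its mechanics (stratum
sizes, recorded rates, exact reduction at rate 1). Unjudged documents count
as grade 0 for exact measures and as unsampled pool members for inferred
ones. Exact NDCG@10, P@10 and AP are cross-checked against an independent
pure-Python reference evaluator shipped under `inst/oracle/`.

## The synthetic benchmark

`generate_benchmark()` emulates the study conditions at desk scale: 2000
documents, 10 topics, three two-token concepts per topic, 10 relevant
(grade 2) and 5 partially relevant (grade 1) documents per topic, 30 judged
nonrelevant documents per topic, Zipf-distributed background text (exponent
1.1, 2000-word pseudo-biomedical vocabulary, mean length 80 tokens) so that
`cf/|C|` is heterogeneous the way real language is — a uniform vocabulary
would hide smoothing behavior. Relevant documents contain all three
concepts, partials exactly two, background documents none (concept tokens
are disjoint from the background vocabulary, so the planted structure is
exact and an oracle ranker achieves NDCG@10 = 1).

Two realism features make the benchmark discriminative:

* a **synonym-only fraction** (default 0.2) of relevant documents express
  every concept only through dictionary synonyms, so retrieval without
  query expansion must miss them — this is what the expansion switch of the
  ablation measures; and
* a **scattered fraction** (default 0.4) of relevant documents express two
  of their three concepts non-contiguously: the concept *tokens* are present
  at full boosted frequency but never adjacent, emulating unnormalized
  concept mentions. Phrase-based Boolean tiering sees only one intact
  concept in these documents and files them below partial documents that
  match two intact phrases — a tier-ordering mistake the within-tier BM25
  cannot repair — while the unigram PSD model, which scores tokens rather
  than phrases, recovers them. This is the mechanism behind the benchmark's
  directional finding (PSD-allwords strictly above the stage-1 ordering in
  mean NDCG@10). Without some such feature the planted construction makes
  the cascade a perfect grade classifier and no re-ranker could improve it.

Concept terms are planted with a frequency multiplier (boost 4); scattering
places tokens in distinct inter-word gaps so no two planted tokens are ever
adjacent, and background words are never stopwords, so the separation
survives analysis. A fraction of relevant documents carry their third
concept only in `additional.summary`, giving the additional-fields switch
its effect. All of this is reproducible byte-for-byte from the seed.

What passing tests on this benchmark do *not* show: performance on real
production-scale data (hundreds of thousands of records, vocabulary overlap
between questions and irrelevant metadata, judgment pools built by pooling
submitted runs), analyzer behavior on real DATS field quirks, or absolute
metric values — only the relative, directional behavior of the methods is
meaningful here.

## Problem sizes and runtime choices

The shipped configuration keeps every computation desk-sized: the default
benchmark indexes 2000 documents in a few seconds; the cap check uses a
5200-document corpus against the 5000-document cap; the PSD oracle
equivalence runs 200 randomized corpora of at most 20 documents; the
estimator validation uses 500 resamples of one 400-document topic. The
pipeline tests use a 300-document, 3-topic variant of the same generator.

## Known limitations

* Concept normalization is not attempted: "TGF-β" in metadata is only found
  if the dictionary lists the variant (the scattered-mention feature of the
  benchmark exists precisely because of this class of miss).
* The dictionary recognizer is a stand-in for a full biomedical named-entity
  mapper; disambiguation is out of scope.
* No positional or bigram postings: ordered/unordered bigram dependence
  models are deliberately not implemented (the unigram PSD variant is the
  point), so phrase matching serves Boolean semantics only.
* The inferred-measure qrels dialect follows the NIST sampling conventions
  (pool membership plus stratum labels, rates implied by sampled fractions);
  other stratification encodings would need translating.
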