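---
title: "expandnet: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{expandnet: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The retrieval-audit model

`expandnet` operationalises a two-stage strategy for finding
user-generated health videos that technical search terms miss, and for
bounding the precision cost of finding them.

**Stage 1 — recall.** A word-embedding model is trained on the
concatenated titles and descriptions of an initial crawl: the *core set*
(videos retrieved directly with the technical focal term) together with
the videos surrounding it on the platform. Terms whose vectors lie
nearest the focal term's vector under cosine similarity are used as new
search queries. The premise is distributional: consumer vocabulary (brand
names of preparation products, merged hashtag words) occurs in the same
narrow contexts as the technical term, while ordinary words are spread
over many contexts. A video retrieved by a neighbour term, judged
relevant by a human coder, and *not* containing the focal term as a token
is a unit of recall improvement — content invisible to the direct query.

**Stage 2 — precision.** Expansion queries also drag in irrelevant
videos. The package exploits the platform's own relatedness graph: for
each coded expansion video it counts distinct directed "related-to" edges
to and from the core set (indegree, outdegree, and their sum, the total
degree). Ranking videos by descending total degree and accumulating
counts yields, at every observed degree value, cumulative precision,
cumulative recall (denominator: all retained relevant videos) and their
harmonic mean F1. The curve tells a coding team what precision it buys at
each recall level before it spends annotation effort.

Assumptions worth stating: relevance codes are exogenous inputs; the
relatedness graph is platform-asserted and treated as ground truth;
degree is used directionlessly (only the sum enters the evaluation, so
the ambiguity of in- versus out-direction in a crawl is harmless); and
non-English videos are excluded from the network stage because a
monolingual core set cannot link to them.

## Text normalization

One fixed recipe (`normalize_text()`): lowercase → transliterate to ASCII
→ split on every non-alphanumeric character → drop empty strings and
stopwords. Points that were genuinely open and how they were fixed:

* *Order of operations.* Stopword removal happens last, after
  tokenization, so the stopword list is matched against the same token
  space it is defined in.
* *Transliteration.* Common Latin diacritics are mapped directly
  (`café → cafe`); glibc's `//TRANSLIT` was rejected because it renders
  accents as apostrophe sequences, which the tokenizer would split into
  spurious tokens. Characters with no ASCII form (emoji, other scripts)
  are dropped.
* *Tokenizer.* Splitting only on non-alphanumerics keeps hashtag
  portmanteaus (`breastcancerawareness`) and digit-bearing product names
  intact; both matter for consumer-vocabulary discovery. No stemming or
  spelling correction, so `colonoscopies` is a different token from
  `colonoscopy` — this also defines the mention check (below).
* *Stopwords.* A packaged ~160-token English list (alphanumeric tokens
  only; contraction fragments listed separately because the apostrophe is
  a split point). The list id is recorded in run manifests. Mention
  detection (`mentions_term()`) deliberately skips stopword removal so a
  focal term that collides with the list is still found.

## Embedding training

The trainer (`train_embeddings()`, compiled C++) implements skip-gram and
CBOW with negative sampling, a linearly decaying learning rate, uniformly
reduced context windows and frequent-word subsampling, single-threaded
over an internal xorshift PRNG so a `(docs, params, seed)` triple is
bit-reproducible. Defaults: `dim = 50`, `window = 5`, `epochs = 5`,
`min_count = 5`, `negative = 5`, `sample = 1e-3`, `alpha = 0.025`.

Two defaults deserve justification:

* *Subsampling (`sample = 1e-3`) is not optional in practice.* In a
  focused crawl the focal term can be several percent of all tokens.
  Without down-sampling it dominates the negative-sampling geometry and
  the neighbour ranking degenerates (we observed planted terms ranked
  *last*). The value is the reference implementation's default.
* *Skip-gram, not CBOW, is the default algorithm.* At desk scale
  (~10⁵ tokens) CBOW with 5 epochs is under-trained: in controlled
  experiments on generated corpora it failed to recover planted
  neighbour terms (median rank ≈ 40) where skip-gram with identical
  hyperparameters recovered them (median rank ≈ 3.5 over 10 seeds);
  CBOW needs ~15 epochs to catch up. Skip-gram's advantage on small
  corpora and rare words is well documented. CBOW remains available via
  `algorithm = "cbow"`.

A caution that belongs in any honest account: word2vec-style neighbour
rankings on corpora this small are seed-sensitive, and *over*-training
can be as harmful as under-training (at 20 epochs both this trainer and
a reference implementation systematically demote rare focal-exclusive
terms below frequent general words). The package treats single-threaded
seeded runs as the reproducible mode; multi-run rank aggregation is left
to the caller.

Ranking (`nearest_neighbors()`) is exact brute-force cosine over the
vocabulary, focal term excluded, ties broken lexicographically. Models
persist in the word2vec text format.

## Corpus comparison statistics

* `build_dfm()` produces raw token counts (no tf-idf): set-level
  distances in the hundreds for a 250-video set against single digits
  among 25-video sets are a *feature* of the count scale and match how
  such tables are conventionally reported. A per-document mode plus
  `set_distance_avg()` (mean over cross-set document pairs) covers the
  alternative reading of "average distance between sets".
* `keyness()` computes the Yates-corrected 2×2 chi-square per term,
  signed by over-representation; the correction is clamped at zero when
  it exceeds `|ad − bc|`, matching `chisq.test(correct = TRUE)`.
* `hcluster_complete()` is an explicit O(n³) agglomeration (fine for the
  handfuls of video sets this is used on) rather than a call to
  `stats::hclust`, so tie-breaking can be fixed: among equal-height
  candidate merges, the pair whose lexicographically smallest member
  labels sort first wins. Output is a standard `hclust` object;
  `stats::hclust` and a from-scratch set-based agglomerator serve as
  independent oracles in the test suite.

## Network evaluation

`exclusion_filter()` operates on the coded expansion sample and assigns
at most one exclusion reason per video with priority
missing-metadata → duplicate-of-core → non-English, so tallies add up to
the sample size. `"und"` language tags are trusted (not excluded) unless
`treat_und_as_non_english = TRUE`. Duplicates are detected as expansion
rows whose id also occurs in the core set; the corpus container
consequently enforces id uniqueness per *(id, set)* pair rather than
globally, because a re-retrieved core video legitimately appears twice.

`threshold_curve()` keeps full-precision percentages internally; display
and CSV output round precision to integers and recall/F1 to one decimal,
with F1 computed *before* rounding (rounding first would visibly corrupt
cells, e.g. producing 76.0 where 75.9 is correct). Rounding is half-up,
the convention of published tables, not IEEE half-even. Only observed
degree values get rows; `precision_at(curve, t)` resolves an unobserved
threshold to the smallest observed degree above it, which is what "at or
above t connections" means operationally.

## The synthetic world

`generate_corpus()` emulates the data a focal-term crawl plus
neighbour-term expansion would return. Text is a bag-of-words mixture:

* a *general* vocabulary (38 words) shared by focal and background
  documents — crucial realism, because no ordinary word occurs only next
  to the focal term in real corpora;
* *background topics* (3 disjoint topic vocabularies, ~66 words each)
  mixed half-and-half with general words in irrelevant documents;
* the focal term plus *planted brand terms*, the only tokens whose
  contexts are almost exclusively focal. Co-occurring core documents
  carry an alternating brand–focal run, mimicking prep-instruction
  descriptions that repeat a product name next to the procedure name;
* a disjoint pseudo-foreign vocabulary for non-English videos.

Scale and rates are the published case study's stated world: 250 core
videos; 6 neighbour terms × 250 retrieved videos of which a random 25 per
term are coded (the 10% coding design); `p_relevant = 0.34`,
`p_mention = 0.59` (≈ 30/51), `p_non_english = 0.187` (28/150),
`p_duplicate = 0.053` (8/150), `p_missing_metadata = 0.007` (1/150).
Edge probabilities `p_edge_rel = 0.0065` and `p_edge_irr = 0.00075` per
core video were chosen once so that the probability of at least one
connection over 250 core videos is ≈ 0.80 for relevant and ≈ 0.17 for
irrelevant videos, the rates implied by the published degree table; they
were not adjusted afterwards. Relatedness is queried for the coded
sample, as a coding team would.

An earlier draft of the generator collapsed each expansion set to its
coded 25 videos; the resulting 400-document corpus made neighbour
recovery seed-flaky for this trainer *and* for a reference word2vec
implementation, while a PPMI-cosine computation confirmed the corpus
statistics themselves were correct. Restoring the full 250-video sets
(≈ 1,750 documents) made recovery exact — the planted terms are the top
six neighbours in every seed tried. The lesson is recorded here because
it bounds what a green test establishes: recovery is demonstrated at the
paper's corpus scale, not at arbitrary miniatures.

What the generator does **not** model: grammar or word order beyond the
planted runs, engagement metadata, topic drift over time, core–core
relatedness structure, coder disagreement, and platform ranking effects.
Green synthetic tests therefore establish that the pipeline's statistics
recover planted co-occurrence, rates and graph contrast — not that the
method works on any particular live platform.

## Numerical and degenerate-input conventions

* Cosine of a zero vector is an error, not NaN; values are clamped to
  [−1, 1] against floating-point drift.
* Vocabulary order is frequency-descending with lexicographic
  tie-break, fixing the negative-sampling table and hence exact
  reproducibility.
* Empty documents are retained (a video whose text is all stopwords
  still exists); documents shrink when out-of-vocabulary tokens are
  dropped but are not re-windowed.
* An all-excluded sample warns and returns an empty retained set; a
  sample with zero relevant videos makes recall undefined and errors.
* Self-loops and duplicate directed edges are dropped at ingestion;
  edges touching ids outside the corpus are kept but marked external and
  never counted.

## Limitations

The embedding stage needs on the order of a thousand documents before
neighbour rankings stabilise; below that, treat any single-seed ranking
as a draw from a noisy distribution. Degree filtering presumes the
platform exposes a relatedness signal aligned with topical relevance —
where it reflects popularity or personalisation instead, the
precision–recall trade-off will be flatter than the curve suggests. The
mention check is exact-token; morphological variants of a focal term
count as omissions, which slightly inflates recall improvement for
languages or terms with rich inflection.
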