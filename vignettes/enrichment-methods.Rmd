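---
title: "Methods: enriching consumer health vocabularies from lay text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enriching consumer health vocabularies from lay text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Professional medical concepts (UMLS concepts, keyed by CUI) are mapped to
the informal terms laypeople actually use by consumer health vocabularies
such as the OAC CHV and the MedlinePlus topics. These mappings are built
and updated mostly by hand, so they grow slowly. `layglove` implements an
automatic enrichment pipeline: given (a) a corpus of lay health
discussion, (b) existing concept-to-layman-term mappings, and (c) a
lexical resource exposing synonym/hyponym/hypernym relations, it proposes
new lay synonyms for each concept and scores the proposals against
held-out known synonyms.

The pipeline is: preprocess the corpus; build a filtered ground-truth
concept set and draw one seed term per concept; optionally expand the
corpus by inserting relational synsets around each seed occurrence; train
GloVe-style word embeddings; rank the vocabulary by cosine similarity to
each seed; evaluate the top-`n` candidates against the held-out synonyms.

## Preprocessing

`preprocess_corpus()` applies a fixed order: lowercase, strip punctuation
(tokens split on any non-alphanumeric character), drop tokens containing
digits entirely, drop general and domain stopwords, stem with the
Snowball English stemmer, then drop tokens shorter than `min_token_len`
(default 3 characters). Stemming before the length filter is what lets a
six-character stem like `fatigu` survive while genuinely short tokens are
removed; stopword matching before stemming avoids stemming the stopword
list itself. The domain stopword default is the four ubiquitous clinical
words `test`, `doctor`, `symptom`, `physician`; users working in other
domains should supply their own list.

The stemmer is a full implementation of the Snowball English (Porter2)
algorithm, authored in this package because no stemming library is
declared as a dependency. Its test suite pins down the published
algorithm's behavior on a frozen reference list plus the canonical
collapse `fatigue/fatigues/fatigued/fatiguing -> fatigu`.

One caveat worth knowing: preprocessing is idempotent on its own output
for ordinary text, but stemming can occasionally map a non-stopword onto
a stopword (`cans -> can`), in which case a second pass would remove the
token. The pipeline never preprocesses twice, so this only matters if
you feed already-tokenized text back in.

## Ground truth and seed terms

`build_ground_truth()` admits a concept when its preferred name is a
unigram and, after stemming, deduplication, and removal of terms equal to
the stemmed preferred name, it retains at least `min_terms = 2` unigram
lay terms each occurring strictly more than `min_freq = 100` times in
the preprocessed corpus. The strict inequality follows the literal
"more than 100 times" reading; a term at exactly 100 is excluded.
Frequencies are taken from the unexpanded corpus: filtering precedes
expansion in the pipeline's flow, so the ground truth does not depend on
which relation is used for expansion.

`assign_seeds()` draws one seed term per concept uniformly at random,
iterating concepts in sorted CUI order from a single RNG stream seeded
once — assignments are reproducible and independent of row order. The
remaining terms become that concept's held-out synonyms.

## Lexical expansion

For each seed term `s`, the lexical resource returns related terms of
one relation kind (synonyms, hyponyms, or hypernyms), unioned over all
senses that contain `s` — no word-sense disambiguation is attempted, so
an ambiguous seed picks up relations from several meanings. Each
candidate is scored by Resnik similarity to the seed: the information
content of the most informative common ancestor, maximized over all
(seed sense, candidate sense) pairs. Scored candidates are sorted by
descending similarity (ties broken lexicographically), truncated to at
most `cap = 10` items, and split into a left subset `X1` and a right
subset `X2`. Every occurrence of `s` in the corpus is then rewritten as
`... X1 s X2 ...`; only original token positions are scanned, so
inserted tokens are never themselves expanded, and deleting the inserted
tokens recovers the original corpus exactly.

Two split modes are provided because the method's description and its
worked example disagree: `"roundrobin"` (the default) deals items
alternately left/right, which actually balances the total similarity
mass of the two sides, while `"halves"` places the top half contiguously
on the left, which is what the worked example shows. The choice is a
configuration flag rather than a guess.

Multi-word lemmas are kept as single underscore-joined tokens
(`dead_weight`), and every lemma component is stemmed with the pipeline
stemmer before insertion, so inserted tokens can unify with corpus
vocabulary entries. A term that seeds several concepts gets exactly one
merged insertion plan, keyed by surface token, to avoid double
insertion. The cap is applied after deduplication across senses.

At the co-occurrence level, the intended effect of expansion is
additive: with flat weighting and a window at least `|X1| + |X2| + 1`
wide, each seed occurrence contributes one co-occurrence count between
the seed and every inserted token, so the seed's expanded co-occurrence
row equals its original row plus the inserted-token contributions. The
test suite asserts exactly this identity on a constructed corpus; with
the default inverse-distance weighting the effect is analogous but
distance-discounted.

## Embeddings

`build_cooccurrence()` accumulates symmetric within-window token-pair
weights in one pass (windows never cross document boundaries); the
weight of a pair at distance `d` is `1` (flat) or `1/d`
(inverse-distance, the default, as in the original GloVe formulation).
`train_embeddings()` minimizes

$$\sum_{i,j:\,X_{ij}>0} f(X_{ij})\,\bigl(w_i^\top \tilde w_j + b_i +
\tilde b_j - \log X_{ij}\bigr)^2,\qquad
f(x) = \min\{(x/x_{\max})^{\alpha}, 1\}$$

by per-coordinate AdaGrad updates over the shuffled nonzero entries of
the full symmetric matrix. The method this package implements names
GloVe but fixes none of the optimizer constants, so the defaults follow
the original GloVe publication: `x_max = 100`, `alpha = 0.75`, learning
rate `0.05`, initialization uniform in `(-0.5/dim, +0.5/dim)`. All
randomness (initialization and shuffling) comes from one self-contained
seeded stream, so a fixed `rng_seed` gives bitwise-identical models.
The exported vector of a token is `w + w~` (main plus context), the
combination the original formulation found best; `which = "main"`
selects `w` alone.

The corpus-scale experiments behind this method favored vector size 400
and window 30 with candidate lists of `n = 10`; those are the
`run_config()` defaults. The package's own test and acceptance runs use
a desk-scale synthetic benchmark (about 60k tokens, vocabulary of a few
hundred types) with `dim = 50`, `window = 10`, `epochs = 20`, which
trains in seconds and is ample for a vocabulary that small.

## Ranking and evaluation

Candidates for a seed are the top-`n` vocabulary tokens by cosine
similarity to the seed's vector, from an exhaustive scan (the vocabulary
is desk-scale; no approximate indexing). Trained vectors can have
negative cosine despite similarity being conventionally described on a
0–1 scale; negative scores are retained and ranked rather than clipped,
since clipping would discard ordering information. Ties break
lexicographically, making rankings fully deterministic. Other seed terms
of the same concept are not excluded from candidate lists — retrieving a
held-out synonym is precisely a success.

A candidate is a true synonym iff its stemmed surface equals a held-out
synonym of the list's concept, with each (concept, synonym) pair counted
at most once. The metrics:

- micro precision = true synonyms found / total candidate terms
  (generated lists × `n`); micro recall = true synonyms found / total
  held-out synonyms in the dataset;
- macro precision = concepts with at least one hit / generated lists;
  macro recall = concepts with at least one hit / dataset concepts;
- F = harmonic mean, defined as 0 when precision = recall = 0;
- NumCon = concepts with at least one hit;
- MRR = mean over generated lists of the reciprocal rank of the first
  hit, with misses contributing 0 (a hits-only variant is available).

The macro precision denominator is the number of *generated* lists, not
all concepts — that reading is forced by the worked scenario the test
suite reproduces (15 hit lists over 20 generated lists from a 25-concept
dataset give precision 0.75). `sweep_candidate_size()` evaluates a range
of `n` values by prefixing a single ranked scan, so micro recall and
NumCon are non-decreasing in `n` by construction, and
`compare_algorithms()` reports the relative macro-F improvement
`(F_b - F_a)/F_a` as an integer percentage, averaging first when two
datasets' reports are given.

The published evaluation framework claims statistical significance
without naming a test; `paired_hit_mcnemar()` is this package's own
choice of a paired exact test on per-concept hit indicators, provided as
supplementary tooling and clearly not part of the original framework.

## The synthetic benchmark

`generate_benchmark()` produces a self-contained corpus + concept TSV +
toy lexical resource with planted synonym groups. Each concept owns a
geometric multinomial over its context tokens; each document picks one
concept and fills slots with context tokens (probability 0.45), that
concept's synonyms (0.25, uniform), and background tokens (0.30), plus
light punctuation/number/stopword noise that preprocessing must remove.
Synonyms of one concept therefore substitute for one another in
identically distributed context slots — the minimal generative process
under which distributional synonymy is identifiable. Defaults: 20
concepts × 3 synonyms, 8 context tokens per concept, 250 background
types, 1,500 documents of 40 tokens (60k tokens), chosen as the smallest
scale at which embedding training is comfortably stable.

Every planted synonym is guaranteed a corpus frequency strictly above
`min_planted_freq = 120` (sampled documents are audited and boosters
appended deterministically from the same RNG stream), so the planted
groups clear the `> 100` ground-truth filter by a margin. Planted tokens
are generated as Snowball fixed points, so raw and stemmed frequencies
coincide. The toy lexicon exposes only a `lexicon_coverage = 0.6`
fraction of each synonym group (as lemmas of one sense per concept,
under a root → branch → concept → narrow-sense taxonomy with fixed
information-content values 0/1.5/4/6), which keeps corpus-derived and
lexicon-derived true positives distinguishable.

What the benchmark does *not* emulate: real lay-health language
(misspellings, multi-word terms, topic drift), polysemy across concepts,
Zipfian frequency profiles, and corpus sparsity at the 100M-token scale.
Passing the recovery tests shows the pipeline's machinery is correct and
that lexical expansion does not hurt an identifiable signal; it does not
certify the corpus-scale accuracy figures of the underlying method,
which depend on the real corpus, licensed vocabularies, and lexical
resource version. On the default benchmark the planted signal is strong
enough that both the basic and the synonym-expanded pipeline recover
essentially all concepts; the directional claim the acceptance suite
asserts is that expansion never degrades macro recall.

## Numerical and design choices

- All ordering ties (candidate ranking, synset ranking) break
  lexicographically; all randomness is routed through named integer
  seeds; pipelines re-run bit-identically.
- The frequency threshold is a strict inequality; the expansion cap
  applies after cross-sense deduplication; degenerate inputs (empty
  corpus, empty matrix, zero-size lists) return empty-but-well-formed
  objects, with warnings where a metric denominator vanishes.
- A seed term absent from the trained vocabulary yields "no list
  generated": it reduces the generated-list count rather than erroring,
  and so feeds the macro precision/recall distinction.
- The Resnik information-content table is a property of the lexical
  resource adapter (the toy resource bundles its own); production use
  against a full WordNet installation requires choosing an IC corpus,
  and all similarity scores — hence splits and downstream metrics — are
  resource-version dependent.

## Known limitations

The pipeline handles unigram seed terms only (multi-word lay terms are
filtered out of the ground truth). Word-sense disambiguation is
deliberately absent; ambiguous seeds import noise from unrelated senses,
mitigated only by the cap and similarity sorting. The stemmer, while a
faithful Porter2 implementation, collapses some distinct medical terms
to one stem, and the idempotence caveat above applies to re-tokenized
input. Finally, evaluation counts only exact stemmed matches against
known synonyms, so genuinely novel lay terms — often the most valuable
output — register as false positives; inspecting the ranked candidate
lists directly remains worthwhile.
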