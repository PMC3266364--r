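---
title: "Extracting gene methylation-cancer relations with methrelex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting gene methylation-cancer relations with methrelex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrelex)
```

## The task and the staged model

Aberrant DNA methylation — hypermethylation of promoter CpG islands or
global hypomethylation — is one of the best-studied epigenetic marks in
cancer, and the literature describing which genes are methylated in
which tumor types grows far faster than curators can read it.
`methrelex` mines PubMed-style abstracts for *gene methylation-cancer*
associations with a staged, hybrid design: rule- and dictionary-based
named entity recognition, followed by two binary maximum-entropy
relation classifiers, followed by probability-based aggregation.

The extraction is deliberately formulated as two binary decisions
rather than one ternary one:

1. **G-M stage.** For every (gene, methylation-term) pair in a sentence,
   decide whether the gene is actually described as methylated.  A
   sentence with several candidate pairs is *duplicated* into several
   instances, each carrying exactly one pair, so the classifier always
   sees a single, unambiguous question.
2. **G-C stage.** Only sentences with at least one positive G-M pair
   proceed.  They are cancer-tagged, each positively-methylated gene is
   paired with each cancer mention, and the second classifier decides
   whether the methylation is tied to that cancer.

Every positive G-C instance becomes an *evidence sentence*.  For a
gene--cancer pair with evidence probabilities $p_1, \dots, p_n$ from the
G-C model, the ranking score and the average maximum probability are

$$\mathrm{score}(G, C) = \sum_{i=1}^{n} p_i, \qquad
  \bar{p}(G, C) = \frac{1}{n}\sum_{i=1}^{n} p_i .$$

The sum rewards both confidence and volume of evidence — a pair
supported by thirty sentences at $p = 0.9$ outranks one supported by a
single certain sentence — while $\bar p$ reports per-sentence
confidence for display.  Adding any evidence sentence with $p_i > 0$
strictly increases the score; this monotonicity is enforced by tests.

## Named entity recognition

Three taggers add mentions to tokenized sentences; a span carries at
most one entity kind, and overlapping candidates are resolved longest
span first, leftmost first.

* **Methylation terms** are matched per token by the case-insensitive
  pattern `(hyper|hypo)?(-)?methylat.+`.  The trailing `.+` requires at
  least one character after the stem inside the token
  (`methylated`, `hypermethylation`; not `methylat`), and the matched
  prefix sets the mention direction (`HYPER`/`HYPO`/`UNSPECIFIED`),
  which later feeds the hyper/hypo statistics of ranked associations.
* **Cancer names** combine a dictionary of canonical multi-word names
  with three surface patterns: (1) case-*sensitive* acronyms
  (`NPC`, `CRC` — case-sensitivity keeps `all` from matching `ALL`);
  (2) an anatomical site followed by a cancer keyword (`breast cancer`,
  keyword list fixed to cancer/tumor/tumour/neoplasm/carcinogenesis/
  tumorigenesis/metastasis); (3) a single token ending in `oma` or
  equal to `leukemia`/`leukaemia`.  For pattern (3) we require at least
  three characters of stem before `oma`: the pattern itself only
  demands one, but one- and two-letter stems admit `soma` and `aroma`,
  so the stricter bound is applied and documented here as a deliberate
  tightening.
* **Gene names** use dictionary lookup over token n-grams,
  case-sensitive first and case-folded second, after expanding each
  dictionary surface through orthographic variant rules (hyphen
  insertion before trailing digits, hyphen removal, case folding —
  `BRCA1` ↔ `BRCA-1` ↔ `brca1`; the variant set is closed under
  re-application).  The tagger interface is pluggable: a statistical
  gene tagger can replace the dictionary without touching downstream
  stages.  The packaged dictionary is a small curated fixture of
  methylation-studied genes intended for testing and demonstration,
  not a genome-wide resource.

NER evaluation supports **exact** matching (identical kind and span)
and **approximate** matching (any same-kind overlap).  Identical spans
are paired first and overlaps second, both greedily left-to-right and
one-to-one, which guarantees approximate precision and recall never
fall below their exact counterparts.

## Features

Each instance is described by named binary features; the groups can be
switched off individually, and removing a group removes exactly its
features (the ablation harness relies on this).

| group | content |
|---|---|
| `NGRAM1`, `NGRAM2` | word uni-/bigrams strictly between the entities |
| `SURROUND_L*`, `SURROUND_R*` | two words before the first / after the second entity, with `<S>` boundary markers |
| `CHUNK_*` | heads and type sequence of shallow chunks between and around the entities |
| `PARSE_PATH` | syntactic path between the entities |
| `SENT_POS` | relative sentence position in the abstract, quintile-bucketed |
| `TEMPLATE` | induced template matches (next section) |
| `ORDER` | whether the gene precedes its partner |

Lexical features are lower-cased and numerals collapse to a `#NUM`
placeholder to limit sparsity; both are toggleable
(`feature_config()`).  Sentence position uses
$r = \mathrm{index}/(\mathrm{total}-1)$ (with $r = 0$ for a
single-sentence abstract) cut into five equal buckets; no finer
discretization is warranted by abstract lengths.  Titles are treated as
sentence 0 of their abstract.

Chunks come from a packaged deterministic shallow parser: a closed-class
word list plus suffix heuristics guesses coarse parts of speech, and a
finite-state pass groups maximal NP/VP runs (PP chunks are the
prepositions themselves).  No full constituency parser ships with the
package, so the default `PARSE_PATH` value is the chunk-type sequence
between the entities prefixed `FALLBACK:`; an external parser adapter
can be plugged into `featurize()` and takes precedence when it
succeeds.  Keeping the default pipeline rule-based makes every feature
deterministic and the test suite self-contained, at the cost of cruder
syntax than a statistical chunker would give.

Entity order inside a pair is normalized to document order for all
context features, with the `ORDER` flag preserving the original
direction.

## Template induction

Relation-bearing phrasings recur: "*X* promoter was hypermethylated in
*Y*", "*X* is frequently methylated in *Z*".  To harvest them, every
positive sentence is *slotified* — entity spans collapse to
`<gene>`/`<methylation>`/`<cancer>` slot tokens, everything else
lower-cased — and all unordered sentence pairs are aligned with
token-level Smith-Waterman local alignment scoring +1 for a match and
−1 for both mismatch and gap.  Slot symbols are ordinary tokens, so
different gene names align as matches while a `<gene>` never matches a
`<cancer>`.  Alignment runs over tokens, not characters: the templates
of interest are token sequences with slots, which character-level
alignment cannot produce.

The pairs are ranked by score (ties broken by the lexicographic order
of the agreement subsequence, then pair indices, making induction
invariant to input order), and each of the top-$k$ pairs ($k = 100$ by
default) contributes its *agreement subsequence* — aligned positions
where both sides carry the same token, gaps elided — as a candidate
template, kept if it contains at least one slot and two tokens.  The
original workflow reviewed the top pairs by hand; that step cannot be
reproduced mechanically, so the agreement filter stands in for it and
`induce_templates(review_path =)` exports the candidate list for
optional human curation.  A matched template fires as a binary
`TEMPLATE` feature when its token sequence occurs *contiguously* in the
slotified sentence; gapped matching was considered and rejected because
it would let short templates fire spuriously across clause boundaries.
All-pairs alignment is quadratic, so inputs beyond a configurable cap
(default 5,000 sentences) are sampled deterministically.

Traceback ties in the alignment prefer matches over gaps and the
maximal cell with the smallest indices, so induced templates are
reproducible to the byte.

## The maximum-entropy classifiers

A conditional maximum-entropy model over binary indicator features is
mathematically identical to logistic regression with a Gaussian prior,
which is how `train_maxent()` implements it: penalized log-likelihood,
analytic gradient over a sparse design matrix, L-BFGS-B optimization.
Defaults: prior variance $\sigma^2 = 1$ (unpenalized intercept),
projected-gradient tolerance $10^{-8}$, decision threshold 0.5 — none
of these is dictated by the underlying method, and all are exposed.
The objective is strictly convex, so restarts from random
initializations agree in their predicted probabilities; the test suite
checks this, verifies the analytic gradient against finite differences,
checks the gradient norm at the returned optimum, and cross-checks
fitted probabilities against an independent ridge-logistic fit
(glmnet) with the penalty mapped as $\lambda = 1/(n\sigma^2)$.

`cross_validate()` performs stratified $k$-fold evaluation
(default $k = 10$) reporting per-fold precision and recall of the
positive class with mean ± sd.  Duplicated instances expanded from the
same source sentence are kept in the same fold; letting near-identical
duplicates straddle the train/test boundary would optimistically bias
the estimate.  A fixed-train-size mode (`train_n`) subsamples each
training split to a set size, supporting protocols that train on a
fixed number of sentences and test on the remainder.

## The synthetic corpus generator

No annotated G-M/G-C corpus is publicly available, so the package
ships a generator (`generate_corpus()`) that emulates the *structure*
of such corpora: labeled single-pair instances over sentences with
gold mention offsets, balanced classes (exact quotas under
`n_instances`), multi-gene sentences that expand into several
instances, and abstracts assembled from the generated sentences.
Defaults mirror the annotated-corpus conditions the pipeline targets:
1,000 positive and 1,000 negative instances per corpus at
`positive_fraction = 0.5`, `signal_strength = 0.9`,
`negation_fraction = 0.3`, `multi_entity_rate = 0.5`, eight sentences
per abstract, and vocabularies drawn from the packaged dictionaries so
generated text round-trips through the taggers.

`signal_strength` is the probability that an instance is realized from
a class-specific cue frame (positive: "*G* promoter methylation was
detected in *C*"; negative: negations and non-relational
co-occurrences) rather than from a *neutral* frame used verbatim by
both classes ("the methylation profile of *G* in *C* was
investigated").  Neutral sentences are irreducibly ambiguous, so the
Bayes precision/recall of a corpus is roughly
$1 - (1 - s)/2$ per class: at $s = 0.9$ a well-fitted classifier
should score in the low-to-mid nineties, and at $s = 1$ exactly 1.0 —
both are asserted in the tests.  Classifier performance is checked to
be monotone in $s$ at three points (0.2, 0.6, 1.0).

The generator targets structural realism, not linguistic realism: real
abstracts have richer syntax, rarer entities, coordination ambiguity
and anaphora that the frames do not model.  Green tests therefore
demonstrate that the machinery is correct and recovers planted signal —
not that the packaged dictionaries or features reach any particular
accuracy on live PubMed text.

## Numerical choices and degenerate inputs

* Character offsets are 0-based half-open throughout, including the
  JSON-lines standoff format; probabilities serialize at full IEEE
  precision (17 significant digits) so corpora round-trip bit-exactly.
* Precision (recall) with an empty denominator is reported as 0 with a
  `degenerate` flag rather than NaN.
* An empty body yields zero sentences; a sentence without entities
  yields zero instances; an all-unseen-feature vector receives the
  fitted prior probability.
* `UNSPECIFIED` methylation directions are counted separately and do
  not contribute to hypermethylation counts.
* Evidence sentences are *not* deduplicated across abstracts before
  summing the ranking score: verbatim repeats in different abstracts
  are independent observations under the sum-of-probabilities reading.

Test and check problem sizes were chosen to exercise each property at
the smallest scale that is statistically meaningful: 2,000-instance
corpora for the headline cross-validation, 300–600 instances for
structural properties, exhaustive alignment-oracle comparison for all
sequence pairs up to length 4 over a 3-symbol alphabet plus a seeded
sample of longer pairs (the full cross-product at length 6 is
astronomically redundant for a 2-parameter scoring scheme).

## Known limitations

* Dictionary-based gene NER cannot find genes absent from the
  dictionary and does not disambiguate symbols that collide with
  common words beyond dictionary membership; the tagger interface is
  the intended extension point.
* The shallow chunker is a heuristic stand-in for full syntax; its
  `PARSE_PATH` fallback carries less information than a true parse
  path.
* Template matching is exact and contiguous; paraphrases beyond the
  induced inventory contribute nothing.
* The ranking score grows with literature volume, so heavily-studied
  pairs dominate; $\bar p$ partially corrects for this but no
  publication-bias adjustment is attempted.
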