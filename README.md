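# methrelex

Text mining of **gene methylation–cancer associations** from
PubMed-style abstracts, for epigenetics researchers and biomedical
text-mining practitioners who need ranked, evidence-backed methylation
profiles rather than raw co-occurrence counts.

Aberrant DNA methylation (promoter hypermethylation, global
hypomethylation) is a candidate diagnostic and prognostic biomarker in
many cancers, and statements linking a gene's methylation status to a
tumor type are scattered across tens of thousands of abstracts.
Co-occurrence mining finds those statements with high recall but many
false positives; `methrelex` instead uses a staged, hybrid design:

1. **Named entity recognition** — a methylation regex
   (`(hyper|hypo)?(-)?methylat.+`, per token, direction-aware), a
   cancer dictionary plus three surface patterns (case-sensitive
   acronyms; *site* + *cancer keyword*; `.+oma|leukemia|leukaemia`),
   and gene dictionary lookup with orthographic variants
   (`BRCA1` ↔ `BRCA-1`).
2. **Sentence expansion** — a sentence with several candidate pairs is
   duplicated into single-pair instances, one (gene, partner) pair per
   instance.
3. **Two maximum-entropy classifiers** — binary G–M ("is this gene
   described as methylated?") then, for positive sentences only, G–C
   ("is the methylation tied to this cancer?"), over binary features:
   inter-entity n-grams, surrounding words, shallow-chunk heads/types,
   parse path, sentence position, and alignment-induced templates.
   Maximum entropy over indicator features is fitted as L2-regularized
   logistic regression (identical model), L-BFGS-B on a sparse design.
4. **Template induction** — positive sentences are slotified
   (`<gene> promoter <methylation>`) and all pairs aligned with
   token-level Smith–Waterman (+1 match, −1 mismatch, −1 gap); the
   agreement subsequences of the top-100 pairs become binary template
   features.
5. **Ranking** — every positive G–C instance is an evidence sentence;
   a (gene, cancer) pair is scored by

   score(G,C) = Σᵢ pᵢ   and   p̄(G,C) = score / n,

   the sum of G–C model probabilities over its n evidence sentences
   and the average maximum probability, with hyper/hypo counts from
   the methylation mention directions.

A deterministic synthetic-corpus generator with controllable
relational signal (`signal_strength`), negation rate and multi-gene
sentence rate makes every stage testable offline.

## Worked example

Tagging and expanding a multi-gene sentence:

```r
library(methrelex)
s1 <- paste0("SOCS1, SOCS2, RASSF1a, CDKN2a, and MGMT were methylated in ",
             "75, 43, 64, 75, and 64% of melanoma samples, respectively.")
sent <- tag_entities(annotated_sentence(s1))
for (m in sent$mentions)
  cat(sprintf("%-12s %-10s [%d,%d) -> %s\n",
              m$kind, m$surface, m$start, m$end, m$normalized_id))
#> GENE         SOCS1      [0,5) -> 8651
#> GENE         SOCS2      [7,12) -> 8835
#> GENE         RASSF1a    [14,21) -> 11186
#> GENE         CDKN2a     [23,29) -> 1029
#> GENE         MGMT       [35,39) -> 4255
#> METHYLATION  methylated [45,55) ->
#> CANCER       melanoma   [86,94) -> melanoma
length(enumerate_pairs(sent, "GM"))
#> [1] 5
```

The five genes are all described as methylated, so the sentence
expands into five single-pair G–M instances (and five G–C pairs with
melanoma downstream).

Training and evaluating on a synthetic corpus, then running the staged
pipeline and ranking:

```r
corp <- generate_corpus(generator_config(seed = 42), n_instances = 2000)
fz <- featurize_corpus(corp$gm)
cross_validate(fz$features, fz$labels, groups = fz$groups, k = 10, seed = 42)
#> 10-fold CV: precision 93.4 +/- 4.6%, recall 95.5 +/- 2.8%

gm <- train_maxent(fz$features, fz$labels, relation_kind = "GM")
fzc <- featurize_corpus(corp$gc)
gc <- train_maxent(fzc$features, fzc$labels, relation_kind = "GC")
ev <- extract_evidence(corp$abstracts[1:40], gm, gc, verbose = TRUE)
#> extract: 320 sentences, 481 G-M pairs (227 positive),
#>          227 G-C pairs (209 positive)
head(rank_associations(ev)[, 1:5], 3)
#>   gene_id       cancer_name ranking_score n_sentences average_max_probability
#> 1    MGMT colorectal cancer      3.992178           4               0.9980445
#> 2    MLH1          leukemia      2.992519           3               0.9975065
#> 3   THBS1     breast cancer      2.990432           3               0.9968107
```

At the default `signal_strength = 0.9`, a tenth of the generated
sentences use neutral phrasing shared by both classes, so
cross-validated precision/recall in the low-to-mid nineties is the
expected ceiling; `MGMT`–colorectal ranks first here because four
evidence sentences each contribute ≈ 1.0 to the summed score.

A thin command-line wrapper over the same functions ships in
`inst/cli/methrelex.R` (subcommands `synth`, `tag`, `induce`, `train`,
`extract`, `rank`, `eval`).

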