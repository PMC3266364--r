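test_that("generation is deterministic given the seed", {
  cfg <- generator_config(seed = 123)
  a <- generate_corpus(cfg, n_instances = 80)
  b <- generate_corpus(cfg, n_instances = 80)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_corpus(a$gm, pa); write_corpus(b$gm, pb)
  expect_identical(readLines(pa), readLines(pb))  # byte-identical
  write_corpus(a$gc, pa); write_corpus(b$gc, pb)
  expect_identical(readLines(pa), readLines(pb))
  # a different seed changes the corpus
  c2 <- generate_corpus(generator_config(seed = 124), n_instances = 80)
  write_corpus(c2$gm, pb)
  expect_false(identical(readLines(pa), readLines(pb)))
})

test_that("instance quotas and label balance are exact", {
  out <- generate_corpus(generator_config(seed = 2, positive_fraction = 0.5),
                         n_instances = 300)
  for (corpus in list(out$gm, out$gc)) {
    labs <- corpus_labels(corpus)
    expect_length(labs, 300)
    expect_equal(sum(labs == "POSITIVE"), 150)
    expect_equal(sum(labs == "NEGATIVE"), 150)
  }
  # uneven fraction rounds the positive quota
  out2 <- generate_corpus(generator_config(seed = 2, positive_fraction = 0.3),
                          n_instances = 100)
  expect_equal(sum(corpus_labels(out2$gm) == "POSITIVE"), 30)
  expect_error(generator_config(gene_vocabulary = character(0)), "non-empty")
})

test_that("generated mentions satisfy the offset and alignment invariants", {
  out <- generate_corpus(generator_config(seed = 77, multi_entity_rate = 2),
                         n_instances = 600)
  sentences <- unique(unlist(lapply(out$abstracts, function(a) a$sentences),
                             recursive = FALSE))
  expect_gt(length(sentences), 200)
  for (s in sentences) {
    expect_silent(validate_sentence(s))
    for (m in s$mentions) {
      expect_identical(m$surface, substr(s$text, m$start + 1, m$end))
      expect_true(m$kind != "METHYLATION" || m$direction %in%
                    c("HYPER", "HYPO", "UNSPECIFIED"))
      expect_true(m$kind == "METHYLATION" || m$direction == "UNSPECIFIED")
    }
    expect_lt(s$sentence_index, s$sentences_in_abstract)
  }
})

test_that("multi-entity sentences expand into the matching number of instances", {
  out <- generate_corpus(generator_config(seed = 15, multi_entity_rate = 4),
                         n_instances = 120)
  texts <- vapply(out$gm$instances, function(i) i$sentence$text, character(1))
  sizes <- table(texts)
  expect_gt(max(sizes), 3)  # multi-gene sentences duplicated per pair
  for (tx in names(sizes)) {
    inst <- out$gm$instances[[match(tx, texts)]]
    k <- vapply(inst$sentence$mentions, function(m) m$kind, character(1))
    expect_equal(unname(sizes[tx]),
                 sum(k == "GENE") * sum(k == "METHYLATION"))
  }
})

test_that("generated surface forms round-trip through the taggers", {
  out <- generate_corpus(generator_config(seed = 33), n_instances = 150)
  glex <- gene_lexicon(); clex <- cancer_lexicon()
  hits <- 0L; total <- 0L
  for (inst in out$gm$instances[1:60]) {
    gold <- inst$sentence
    pred <- tag_entities(annotated_sentence(
      gold$text, sentence_index = gold$sentence_index,
      sentences_in_abstract = gold$sentences_in_abstract), glex, clex)
    gk <- mentions_frame(list(gold)); pk <- mentions_frame(list(pred))
    r <- evaluate_mentions(gk, pk, "EXACT")
    hits <- hits + r$true_positives
    total <- total + nrow(gk)
  }
  expect_gt(hits / total, 0.95)  # taggers recover the gold annotation
})

test_that("classifier performance rises with signal strength", {
  f1_at <- function(s) {
    out <- generate_corpus(generator_config(seed = 50, signal_strength = s),
                           n_instances = 400)
    fz <- featurize_corpus(out$gm)
    cv <- cross_validate(fz$features, fz$labels, groups = fz$groups,
                         k = 5, seed = 5)
    p <- attr(cv, "mean_precision"); r <- attr(cv, "mean_recall")
    2 * p * r / (p + r)
  }
  scores <- vapply(c(0.2, 0.6, 1.0), f1_at, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_equal(scores[3], 1)  # fully separable at signal 1
})

test_that("a fully cued corpus is perfectly separable under maxent defaults", {
  out <- generate_corpus(
    generator_config(seed = 9, signal_strength = 1, negation_fraction = 0),
    n_instances = 300)
  for (corpus in list(out$gm, out$gc)) {
    fz <- featurize_corpus(corpus)
    cv <- cross_validate(fz$features, fz$labels, groups = fz$groups,
                         k = 10, seed = 6)
    expect_equal(attr(cv, "mean_precision"), 1)
    expect_equal(attr(cv, "mean_recall"), 1)
  }
})

test_that("template features add a measurable, reported cross-validation delta", {
  out <- generate_corpus(generator_config(seed = 44), n_instances = 300)
  pos <- Filter(function(i) i$label == "POSITIVE", out$gm$instances)
  tpl <- induce_templates(lapply(pos, `[[`, "sentence"), top_k = 100)
  expect_gt(length(tpl), 0)
  fz_plain <- featurize_corpus(out$gm)
  fz_tpl <- featurize_corpus(out$gm, templates = tpl)
  # the TEMPLATE group fires on at least some instances
  n_hits <- sum(vapply(fz_tpl$features, function(f)
    any(startsWith(f, "TEMPLATE=")), logical(1)))
  expect_gt(n_hits, 0)
  # and is the only difference between the two featurizations
  for (i in seq_along(fz_plain$features)) {
    expect_identical(setdiff(fz_tpl$features[[i]], fz_plain$features[[i]]),
                     grep("^TEMPLATE=", fz_tpl$features[[i]], value = TRUE))
  }
  cv_plain <- cross_validate(fz_plain$features, fz_plain$labels,
                             groups = fz_plain$groups, k = 5, seed = 44)
  cv_tpl <- cross_validate(fz_tpl$features, fz_tpl$labels,
                           groups = fz_tpl$groups, k = 5, seed = 44)
  delta_p <- attr(cv_tpl, "mean_precision") - attr(cv_plain, "mean_precision")
  delta_r <- attr(cv_tpl, "mean_recall") - attr(cv_plain, "mean_recall")
  expect_true(is.finite(delta_p) && is.finite(delta_r))
  # on a strongly cued corpus the lexical features already separate the
  # classes, so the template delta stays small
  expect_lt(max(abs(delta_p), abs(delta_r)), 0.1)
})

test_that("the trained model recovers cue-phrase n-grams as top positive weights", {
  out <- generate_corpus(generator_config(seed = 18, signal_strength = 0.95),
                         n_instances = 500)
  m <- train_maxent_from(out$gm)
  top <- names(sort(m$weights, decreasing = TRUE))[1:10]
  cue_words <- c("frequently", "promoter", "aberrant", "observed",
                 "respectively", "detected", "were", "methylated")
  is_cue_ngram <- grepl("^NGRAM[12]=", top) &
    grepl(paste(cue_words, collapse = "|"), top)
  expect_gte(sum(is_cue_ngram), 4)
})
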