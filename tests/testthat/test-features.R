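test_that("inter-entity n-grams follow the between-span rule", {
  s1 <- s1_tagged()
  pairs <- enumerate_pairs(s1, "GM")
  genes <- vapply(pairs, function(p) p$first_entity$surface, character(1))
  # (MGMT, methylated): only "were" lies between, so one unigram, no bigram
  f <- ngram_features(pairs[[which(genes == "MGMT")]])
  expect_setequal(f, "NGRAM1=were")
  # (SOCS1, methylated): many tokens between, including bigrams
  f1 <- ngram_features(pairs[[which(genes == "SOCS1")]])
  expect_true("NGRAM1=were" %in% f1)
  expect_true("NGRAM2=and_mgmt" %in% f1)
  expect_gt(length(f1), length(f))

  # adjacent entities -> no n-gram features
  s <- tag_entities(annotated_sentence("MGMT methylation was assessed."))
  p <- enumerate_pairs(s, "GM")[[1]]
  expect_length(ngram_features(p), 0)

  # 3 tokens between -> 3 unigrams + 2 bigrams
  s <- tag_entities(annotated_sentence("MGMT can not be methylated here."))
  p <- enumerate_pairs(s, "GM")[[1]]
  f <- ngram_features(p)
  expect_equal(sum(startsWith(f, "NGRAM1=")), 3)
  expect_equal(sum(startsWith(f, "NGRAM2=")), 2)
})

test_that("surrounding words honor positions and boundary markers", {
  s1 <- s1_tagged()
  pairs <- enumerate_pairs(s1, "GM")
  genes <- vapply(pairs, function(p) p$first_entity$surface, character(1))
  f <- surrounding_word_features(pairs[[which(genes == "MGMT")]])
  expect_true("SURROUND_R1=in" %in% f)
  expect_true("SURROUND_R2=#NUM" %in% f)
  # with the numeral placeholder off the raw token appears
  f_raw <- surrounding_word_features(
    pairs[[which(genes == "MGMT")]],
    config = feature_config(num_placeholder = FALSE))
  expect_true("SURROUND_R2=75" %in% f_raw)
  # sentence-initial first entity gets boundary markers on the left
  f_socs <- surrounding_word_features(pairs[[which(genes == "SOCS1")]])
  expect_true("SURROUND_L1=<S>" %in% f_socs)
  expect_true("SURROUND_L2=<S>" %in% f_socs)
  # entity at the very end of the sentence gets right boundary markers
  s <- tag_entities(annotated_sentence("Methylation silenced MGMT"))
  p <- enumerate_pairs(s, "GM")[[1]]
  f <- surrounding_word_features(p)
  expect_true("SURROUND_R1=<S>" %in% f)
  expect_true("SURROUND_R2=<S>" %in% f)
})

test_that("chunk features expose inter-entity heads and types", {
  s <- tag_entities(annotated_sentence(
    "The MGMT gene was frequently methylated in breast tumors."))
  p <- enumerate_pairs(s, "GM")[[1]]
  ch <- chunk_sentence(s)
  f <- chunk_features(p, ch)
  # gene NP and methylation VP are adjacent chunks -> empty type sequence
  expect_true("CHUNK_TYPE_INTER=" %in% f)
  expect_true(any(startsWith(f, "CHUNK_HEAD_SURROUND_")))
  # a VP chunk between the entities surfaces its verb head
  s2 <- tag_entities(annotated_sentence(
    "MGMT silencing was linked with promoter methylation here."))
  p2 <- enumerate_pairs(s2, "GM")[[1]]
  f2 <- chunk_features(p2)
  expect_true(any(grepl("^CHUNK_TYPE_INTER=.+", f2)))
  expect_true(any(startsWith(f2, "CHUNK_HEAD_INTER=")))
  # determinism
  expect_identical(chunk_features(p2), chunk_features(p2))
})

test_that("the fallback parse path reflects the chunk sequence and swaps cleanly", {
  s <- tag_entities(annotated_sentence(
    "MGMT silencing was linked with promoter methylation here."))
  p <- enumerate_pairs(s, "GM")[[1]]
  f <- parse_path_feature(p)
  expect_length(f, 1)
  expect_true(startsWith(f, "PARSE_PATH=FALLBACK:"))
  # a parser adapter takes precedence; on failure the fallback returns
  f2 <- parse_path_feature(p, parser = function(s, a, b) "NP^S_VP")
  expect_equal(f2, "PARSE_PATH=NP^S_VP")
  f3 <- parse_path_feature(p, parser = function(s, a, b) stop("boom"))
  expect_identical(f3, f)
})

test_that("sentence position is bucketed into quintiles", {
  mk <- function(idx, total) {
    s <- tag_entities(annotated_sentence("MGMT was methylated.",
                                         sentence_index = idx,
                                         sentences_in_abstract = total))
    enumerate_pairs(s, "GM")[[1]]
  }
  expect_equal(sentence_position_feature(mk(0, 10)), "SENT_POS=Q1")
  expect_equal(sentence_position_feature(mk(9, 10)), "SENT_POS=Q5")
  expect_equal(sentence_position_feature(mk(0, 1)), "SENT_POS=Q1")
  expect_equal(sentence_position_feature(mk(4, 10)), "SENT_POS=Q3")
})

test_that("featurize composes groups deterministically and supports ablation", {
  s1 <- s1_tagged()
  pairs <- enumerate_pairs(s1, "GM")
  genes <- vapply(pairs, function(p) p$first_entity$surface, character(1))
  p_mgmt <- pairs[[which(genes == "MGMT")]]
  f <- featurize(p_mgmt)
  expect_true("NGRAM1=were" %in% f)
  expect_true("SENT_POS=Q1" %in% f)
  expect_identical(f, featurize(p_mgmt))  # purity
  # different pairs from the same sentence get different context features
  f_socs <- featurize(pairs[[which(genes == "SOCS1")]])
  expect_false(setequal(f, f_socs))
  # removing a group removes exactly that group
  cfg <- feature_config(groups = setdiff(feature_config()$groups, "NGRAM1"))
  f_no1 <- featurize(p_mgmt, config = cfg)
  expect_identical(setdiff(f, f_no1), "NGRAM1=were")
  # no templates loaded -> no TEMPLATE features, everything else unchanged
  expect_length(grep("^TEMPLATE=", f), 0)
})

test_that("template features fire when a template matches the slotified sentence", {
  tpl <- induce_templates(list(
    c("x", "<gene>", "promoter", "<methylation>", "y"),
    c("z", "<gene>", "promoter", "<methylation>", "w")), top_k = 10)
  expect_gte(length(tpl), 1)
  s <- tag_entities(annotated_sentence("The MGMT promoter methylation was clear."))
  p <- enumerate_pairs(s, "GM")[[1]]
  f <- template_features(p, tpl)
  expect_length(f, 1)
  expect_true(startsWith(f[1], "TEMPLATE=t"))
  # a sentence without the pattern gets no template features
  s2 <- tag_entities(annotated_sentence("MGMT was methylated."))
  p2 <- enumerate_pairs(s2, "GM")[[1]]
  expect_length(template_features(p2, tpl), 0)
})

test_that("sparse text feature files round-trip", {
  out <- generate_corpus(generator_config(seed = 9), n_instances = 10)
  fz <- featurize_corpus(out$gm)
  path <- withr::local_tempfile(fileext = ".txt")
  write_sparse_features(fz$features, fz$labels, path)
  back <- read_sparse_features(path)
  expect_identical(back$labels, fz$labels)
  expect_identical(back$features, fz$features)
})
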