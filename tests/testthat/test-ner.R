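test_that("the methylation regex tags full-token matches with direction", {
  cases <- list(
    list("methylated",        TRUE,  "UNSPECIFIED"),
    list("methylation",       TRUE,  "UNSPECIFIED"),
    list("hypermethylation",  TRUE,  "HYPER"),
    list("hypomethylation",   TRUE,  "HYPO"),
    list("hypo-methylated",   TRUE,  "HYPO"),
    list("Hypermethylated",   TRUE,  "HYPER"),
    list("methylat",          FALSE, NA),   # .+ needs >= 1 trailing char
    list("methods",           FALSE, NA),
    list("unmethylated",      FALSE, NA)    # prefix outside the pattern
  )
  for (cs in cases) {
    s <- tag_methylation(annotated_sentence(paste("token", cs[[1]], "end")))
    kinds <- vapply(s$mentions, function(m) m$kind, character(1))
    if (cs[[2]]) {
      expect_equal(sum(kinds == "METHYLATION"), 1, info = cs[[1]])
      m <- s$mentions[[which(kinds == "METHYLATION")]]
      expect_equal(m$direction, cs[[3]], info = cs[[1]])
      expect_equal(m$surface, cs[[1]])
    } else {
      expect_equal(sum(kinds == "METHYLATION"), 0, info = cs[[1]])
    }
  }
})

test_that("methylation tagging is idempotent", {
  s <- annotated_sentence("MGMT was hypermethylated in tumors.")
  once <- tag_methylation(s)
  twice <- tag_methylation(once)
  expect_identical(once$mentions, twice$mentions)
})

test_that("cancer tagging applies the dictionary and three patterns with case rules", {
  lex <- cancer_lexicon()
  tag1 <- function(text) {
    s <- tag_cancer(annotated_sentence(text), lex)
    Filter(function(m) m$kind == "CANCER", s$mentions)
  }
  # (1) abbreviation is case-SENSITIVE
  m <- tag1("Samples from NPC patients were collected.")
  expect_length(m, 1)
  expect_equal(m[[1]]$rule, "abbreviation")
  expect_equal(m[[1]]$normalized_id, "nasopharyngeal carcinoma")
  expect_length(tag1("Samples from npc patients were collected."), 0)
  # (2) tumor site + cancer keyword, case-insensitive
  m <- tag1("Breast Cancer incidence was high.")
  expect_length(m, 1)
  expect_equal(m[[1]]$rule, "site_keyword")
  expect_equal(m[[1]]$surface, "Breast Cancer")
  # (3) suffix pattern with a >= 3 character stem
  m <- tag1("Cells from melanoma were cultured.")
  expect_length(m, 1)
  expect_equal(m[[1]]$rule, "suffix")
  m <- tag1("Patients with leukaemia were enrolled.")
  expect_length(m, 1)
  expect_length(tag1("The soma and the aroma were unaffected."), 0)
  # dictionary names match case-insensitively, longest span first
  m <- tag1("We reviewed hepatocellular carcinoma cases.")
  expect_length(m, 1)
  expect_equal(m[[1]]$rule, "dictionary")
  expect_equal(m[[1]]$surface, "hepatocellular carcinoma")
  # every accepted mention records exactly one originating rule
  s <- tag_cancer(annotated_sentence(
    "NPC and breast cancer and melanoma were compared."), lex)
  rules <- vapply(Filter(function(m) m$kind == "CANCER", s$mentions),
                  function(m) m$rule, character(1))
  expect_setequal(rules, c("abbreviation", "site_keyword", "suffix"))
})

test_that("overlapping cancer candidates resolve longest-span-first", {
  lex <- cancer_lexicon()
  # "nasopharyngeal carcinoma": dictionary 2-token span beats the
  # single-token suffix match on "carcinoma"
  s <- tag_cancer(annotated_sentence(
    "A nasopharyngeal carcinoma cohort was assembled."), lex)
  cm <- Filter(function(m) m$kind == "CANCER", s$mentions)
  expect_length(cm, 1)
  expect_equal(cm[[1]]$surface, "nasopharyngeal carcinoma")
})

test_that("gene variant generation applies the orthographic rules and is closed", {
  v <- generate_variants("BRCA1")
  expect_true("BRCA-1" %in% v)
  expect_true("brca1" %in% v)
  expect_true("BRCA1" %in% v)
  expect_true("BRCA1" %in% generate_variants("BRCA-1"))  # hyphen removal
  v53 <- generate_variants("TP53")
  expect_true(all(c("TP-53", "tp53") %in% v53))
  # closure: re-applying to every variant adds nothing new
  again <- sort(unique(unlist(lapply(v53, generate_variants))))
  expect_identical(again, v53)
})

test_that("gene tagging normalizes through the dictionary", {
  lex <- gene_lexicon()
  s <- tag_genes(annotated_sentence("MGMT was silenced."), lex)
  gm <- Filter(function(m) m$kind == "GENE", s$mentions)
  expect_length(gm, 1)
  expect_equal(gm[[1]]$normalized_id, "4255")
  # two comma-separated symbols give two mentions
  s <- tag_genes(annotated_sentence("SOCS1, SOCS2 were examined."), lex)
  expect_length(Filter(function(m) m$kind == "GENE", s$mentions), 2)
  # hyphen variant resolves to the same identifier as the base symbol
  s <- tag_genes(annotated_sentence("BRCA-1 carriers were recruited."), lex)
  gm <- Filter(function(m) m$kind == "GENE", s$mentions)
  expect_equal(gm[[1]]$normalized_id, "672")
  # tokens absent from the dictionary are not tagged
  s <- tag_genes(annotated_sentence("NOTAGENE was present."), lex)
  expect_length(Filter(function(m) m$kind == "GENE", s$mentions), 0)
})

test_that("mention evaluation counts exact and approximate matches", {
  gold <- data.frame(sentence_id = 1, kind = "CANCER", start = 10, end = 25)
  pred_exact <- gold
  r <- evaluate_mentions(gold, pred_exact, "EXACT")
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  # prediction strictly inside the gold span: approximate TP, exact miss
  pred_in <- data.frame(sentence_id = 1, kind = "CANCER", start = 12, end = 20)
  expect_equal(evaluate_mentions(gold, pred_in, "EXACT")$true_positives, 0)
  expect_equal(evaluate_mentions(gold, pred_in, "APPROXIMATE")$true_positives, 1)
  # the printed-formula example: TP=9 FP=1 FN=3
  gold12 <- data.frame(sentence_id = 1:12, kind = "GENE",
                       start = 0, end = 4)
  pred10 <- data.frame(sentence_id = c(1:9, 99), kind = "GENE",
                       start = 0, end = 4)
  r <- evaluate_mentions(gold12, pred10, "EXACT")
  expect_equal(r$true_positives, 9)
  expect_equal(r$false_positives, 1)
  expect_equal(r$false_negatives, 3)
  expect_equal(r$precision, 0.9)
  expect_equal(r$recall, 0.75)
})

test_that("approximate matching never scores below exact matching", {
  set.seed(81)
  for (rep in 1:40) {
    n_gold <- sample(1:8, 1); n_pred <- sample(1:8, 1)
    mk <- function(n) {
      st <- sample(0:40, n, replace = TRUE)
      data.frame(sentence_id = sample(1:3, n, replace = TRUE),
                 kind = sample(c("GENE", "CANCER"), n, replace = TRUE),
                 start = st, end = st + sample(1:6, n, replace = TRUE))
    }
    gold <- mk(n_gold); pred <- mk(n_pred)
    ex <- evaluate_mentions(gold, pred, "EXACT")
    ap <- evaluate_mentions(gold, pred, "APPROXIMATE")
    expect_gte(ap$precision, ex$precision)
    expect_gte(ap$recall, ex$recall)
  }
})
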