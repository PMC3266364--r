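# Brute-force local alignment oracle: enumerates every monotone
# matching between the two token sequences and scores it directly
# (+1 match, -1 mismatch, -1 per unmatched position inside the aligned
# windows).  No dynamic programming: this is the independent check for
# local_align().
bf_local_align <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- 0
  score_matching <- function(is, ks) {
    sc <- sum(ifelse(a[is] == b[ks], 1, -1))
    gaps_a <- (max(is) - min(is) + 1L) - length(is)
    gaps_b <- (max(ks) - min(ks) + 1L) - length(ks)
    sc - gaps_a - gaps_b
  }
  rec <- function(ai, bi, is, ks) {
    if (length(is)) best <<- max(best, score_matching(is, ks))
    if (ai > n || bi > m) return(invisible())
    for (i in ai:n) {
      for (k in bi:m) {
        rec(i + 1L, k + 1L, c(is, i), c(ks, k))
      }
    }
    invisible()
  }
  rec(1L, 1L, integer(0), integer(0))
  best
}

# the multi-gene worked example sentence used throughout the tests
s1_text <- function() {
  paste0("SOCS1, SOCS2, RASSF1a, CDKN2a, and MGMT were methylated in ",
         "75, 43, 64, 75, and 64% of melanoma samples, respectively.")
}

s1_tagged <- function() {
  tag_entities(annotated_sentence(s1_text()))
}

# oracle classifiers for pipeline tests
always_positive <- function(feats) 1
always_negative <- function(feats) 0

# featurize a corpus and train a model on it in one step
train_maxent_from <- function(corpus, templates = NULL, ...) {
  fz <- featurize_corpus(corpus, templates = templates)
  train_maxent(fz$features, fz$labels,
               relation_kind = corpus$relation_kind, ...)
}
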