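# Named entity taggers: methylation terms (regex), cancer names
# (dictionary + three surface patterns), gene names (dictionary lookup
# with orthographic variants), and mention-level evaluation.

METHYLATION_REGEX <- "^(hyper|hypo)?(-)?methylat.+$"

# add candidate mentions to a sentence, skipping spans overlapping any
# existing mention (single kind per span); candidates resolved
# longest-span-first, ties leftmost-first
add_mentions <- function(sentence, candidates) {
  if (!length(candidates)) return(sentence)
  spans <- lapply(sentence$mentions, function(m) c(m$start, m$end))
  ord <- order(-vapply(candidates, function(m) m$end - m$start, integer(1)),
               vapply(candidates, function(m) m$start, integer(1)))
  for (m in candidates[ord]) {
    clash <- any(vapply(spans, function(s) m$start < s[2] && s[1] < m$end,
                        logical(1)))
    if (!clash) {
      sentence$mentions <- c(sentence$mentions, list(m))
      spans <- c(spans, list(c(m$start, m$end)))
    }
  }
  ord2 <- order(vapply(sentence$mentions, function(m) m$start, integer(1)),
                vapply(sentence$mentions, function(m) m$end, integer(1)))
  sentence$mentions <- sentence$mentions[ord2]
  sentence
}

#' Tag methylation terms
#'
#' Adds a METHYLATION mention for every token whose full surface matches
#' the pattern \code{(hyper|hypo)?(-)?methylat.+} case-insensitively.
#' The trailing \code{.+} requires at least one character after
#' \code{methylat} and is bounded by the token end.  Direction is
#' \code{HYPER} or \code{HYPO} when the prefix matched, otherwise
#' \code{UNSPECIFIED}.
#'
#' @param sentence an \code{\link{annotated_sentence}}.
#' @return the sentence with METHYLATION mentions added.
#' @export
tag_methylation <- function(sentence) {
  tk <- sentence$tokens
  cands <- list()
  for (i in seq_len(nrow(tk))) {
    s <- tk$surface[i]
    if (grepl(METHYLATION_REGEX, s, ignore.case = TRUE)) {
      pre <- tolower(sub("^(hyper|hypo)?(-)?methylat.+$", "\\1", s,
                         ignore.case = TRUE))
      dir <- switch(pre, hyper = "HYPER", hypo = "HYPO", "UNSPECIFIED")
      cands[[length(cands) + 1L]] <- entity_mention(
        "METHYLATION", tk$start[i], tk$end[i], s,
        direction = dir, rule = "regex")
    }
  }
  add_mentions(sentence, cands)
}

#' Tag cancer mentions
#'
#' Combines dictionary lookup with three surface patterns:
#' \enumerate{
#'   \item case-sensitive abbreviation match (\code{NPC}, \code{CRC}, ...);
#'   \item a tumor-site term immediately followed by a cancer-related
#'     keyword (\code{breast cancer}), case-insensitive;
#'   \item a single token matching \code{.+oma}, \code{leukemia} or
#'     \code{leukaemia}, case-insensitive, requiring at least three
#'     characters of stem before \code{oma} to suppress short-stem noise
#'     (\code{soma}, \code{aroma}).
#' }
#' Canonical multi-word dictionary names are matched case-insensitively,
#' longest span first.  Overlapping candidates are resolved longest-span
#' first, leftmost first; each accepted mention records the rule that
#' produced it.
#'
#' @param sentence an \code{\link{annotated_sentence}}.
#' @param lexicon a \code{\link{cancer_lexicon}}.
#' @return the sentence with CANCER mentions added.
#' @export
tag_cancer <- function(sentence, lexicon = cancer_lexicon()) {
  tk <- sentence$tokens
  n <- nrow(tk)
  if (n == 0) return(sentence)
  lower <- tolower(tk$surface)
  cands <- list()
  push <- function(i, j, norm, rule) {
    cands[[length(cands) + 1L]] <<- entity_mention(
      "CANCER", tk$start[i], tk$end[j],
      slice0(sentence$text, tk$start[i], tk$end[j]),
      normalized_id = norm, rule = rule)
  }
  # dictionary: longest n-gram match against canonical names
  name_words <- strsplit(lexicon$canonical_names, " ", fixed = TRUE)
  max_len <- max(lengths(name_words), 1L)
  for (i in seq_len(n)) {
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      j <- i + len - 1L
      cand <- paste(lower[i:j], collapse = " ")
      if (cand %in% lexicon$canonical_names) {
        push(i, j, cand, "dictionary")
        break
      }
    }
  }
  for (i in seq_len(n)) {
    s <- tk$surface[i]
    # (1) abbreviation, case-sensitive
    if (s %in% names(lexicon$abbreviations)) {
      push(i, i, tolower(lexicon$abbreviations[[s]]), "abbreviation")
    }
    # (2) site + keyword
    if (i < n && lower[i] %in% lexicon$site_terms &&
        lower[i + 1L] %in% lexicon$keyword_terms) {
      push(i, i + 1L, paste(lower[i], lower[i + 1L]), "site_keyword")
    }
    # (3) .+oma | leukemia | leukaemia, stem >= 3 before "oma"
    if (lower[i] %in% c("leukemia", "leukaemia") ||
        grepl("^.{3,}oma$", lower[i])) {
      push(i, i, lower[i], "suffix")
    }
  }
  add_mentions(sentence, cands)
}

#' Tag gene mentions
#'
#' Longest-match dictionary lookup over token n-grams, case-sensitive
#' first then case-insensitive, with orthographic variants expanded at
#' lexicon build time.  Each mention carries the gene identifier from
#' the lexicon as \code{normalized_id}.
#'
#' @param sentence an \code{\link{annotated_sentence}}.
#' @param lexicon a \code{\link{gene_lexicon}}.
#' @return the sentence with GENE mentions added.
#' @export
tag_genes <- function(sentence, lexicon = gene_lexicon()) {
  tk <- sentence$tokens
  n <- nrow(tk)
  if (n == 0) return(sentence)
  cands <- list()
  for (i in seq_len(n)) {
    for (len in rev(seq_len(min(lexicon$max_ngram, n - i + 1L)))) {
      j <- i + len - 1L
      surf <- slice0(sentence$text, tk$start[i], tk$end[j])
      id <- gene_lookup(lexicon, surf)
      if (!is.na(id)) {
        cands[[length(cands) + 1L]] <- entity_mention(
          "GENE", tk$start[i], tk$end[j], surf,
          normalized_id = id, rule = "dictionary")
        break
      }
    }
  }
  add_mentions(sentence, cands)
}

#' Tag all entity kinds
#'
#' Convenience wrapper running \code{\link{tag_methylation}},
#' \code{\link{tag_genes}} and \code{\link{tag_cancer}} in that order
#' (earlier kinds claim overlapping spans first).
#'
#' @param sentence an \code{\link{annotated_sentence}}.
#' @param gene_lex a \code{\link{gene_lexicon}}.
#' @param cancer_lex a \code{\link{cancer_lexicon}}.
#' @param kinds subset of \code{c("methylation", "gene", "cancer")}.
#' @return the tagged sentence.
#' @export
tag_entities <- function(sentence, gene_lex = gene_lexicon(),
                         cancer_lex = cancer_lexicon(),
                         kinds = c("methylation", "gene", "cancer")) {
  if ("methylation" %in% kinds) sentence <- tag_methylation(sentence)
  if ("gene" %in% kinds) sentence <- tag_genes(sentence, gene_lex)
  if ("cancer" %in% kinds) sentence <- tag_cancer(sentence, cancer_lex)
  sentence
}

#' Evaluate predicted mentions against gold
#'
#' Under \code{EXACT} matching a true positive requires identical
#' (kind, start, end); under \code{APPROXIMATE} any same-kind overlap of
#' at least one character counts.  Matching is greedy left-to-right and
#' one-to-one: each gold mention matches at most one prediction and vice
#' versa.  Precision is TP/(TP+FP) and recall TP/(TP+FN); a zero
#' denominator is reported as 0 with \code{degenerate = TRUE}.
#'
#' @param gold,predicted data.frames with columns \code{sentence_id},
#'   \code{kind}, \code{start}, \code{end} (one row per mention), or
#'   lists of \code{annotated_sentence}s paired by position (converted
#'   with \code{\link{mentions_frame}}).
#' @param strategy \code{"EXACT"} or \code{"APPROXIMATE"}.
#' @return an object of class \code{match_result} with counts,
#'   \code{precision}, \code{recall} and \code{strategy}.
#' @export
evaluate_mentions <- function(gold, predicted,
                              strategy = c("EXACT", "APPROXIMATE")) {
  strategy <- match.arg(strategy)
  if (!is.data.frame(gold)) gold <- mentions_frame(gold)
  if (!is.data.frame(predicted)) predicted <- mentions_frame(predicted)
  ordm <- function(d) d[order(d$sentence_id, d$start, d$end), , drop = FALSE]
  gold <- ordm(gold); predicted <- ordm(predicted)
  used_gold <- rep(FALSE, nrow(gold))
  used_pred <- rep(FALSE, nrow(predicted))
  match_pass <- function(test) {
    for (i in seq_len(nrow(predicted))) {
      if (used_pred[i]) next
      p <- predicted[i, ]
      for (j in seq_len(nrow(gold))) {
        if (used_gold[j]) next
        g <- gold[j, ]
        if (g$sentence_id != p$sentence_id || g$kind != p$kind) next
        if (test(g, p)) {
          used_gold[j] <<- TRUE; used_pred[i] <<- TRUE
          break
        }
      }
    }
  }
  # identical spans pair up first; APPROXIMATE then admits any overlap,
  # so its match set always contains the exact one
  match_pass(function(g, p) g$start == p$start && g$end == p$end)
  if (strategy == "APPROXIMATE") {
    match_pass(function(g, p) p$start < g$end && g$start < p$end)
  }
  tp <- sum(used_pred)
  fp <- nrow(predicted) - tp
  fn <- nrow(gold) - tp
  match_result(tp, fp, fn, strategy)
}

match_result <- function(tp, fp, fn, strategy) {
  structure(
    list(true_positives = tp, false_positives = fp, false_negatives = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else 0,
         recall = if (tp + fn > 0) tp / (tp + fn) else 0,
         degenerate = (tp + fp == 0) || (tp + fn == 0),
         strategy = strategy),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result %s> TP=%d FP=%d FN=%d P=%.3f R=%.3f\n",
              x$strategy, x$true_positives, x$false_positives,
              x$false_negatives, x$precision, x$recall))
  invisible(x)
}

#' Flatten sentence mentions into a data.frame
#'
#' @param sentences list of \code{\link{annotated_sentence}}s; the list
#'   position is used as \code{sentence_id}.
#' @return data.frame with columns \code{sentence_id}, \code{kind},
#'   \code{start}, \code{end}, \code{surface}.
#' @export
mentions_frame <- function(sentences) {
  rows <- list()
  for (i in seq_along(sentences)) {
    for (m in sentences[[i]]$mentions) {
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = i, kind = m$kind, start = m$start, end = m$end,
        surface = m$surface, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sentence_id = integer(0), kind = character(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
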