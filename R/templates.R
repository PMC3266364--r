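# Template induction: slotify tagged sentences, align all positive
# sentence pairs with token-level Smith-Waterman (+1 match, -1 mismatch,
# -1 gap), and turn the agreement subsequence of each top-scoring pair
# into a slot-bearing template used as a binary feature.

SLOT_SYMBOLS <- c(GENE = "<gene>", METHYLATION = "<methylation>",
                  CANCER = "<cancer>")

#' Replace entity spans by slot symbols
#'
#' Collapses each entity mention span to a single slot token
#' (\code{<gene>}, \code{<methylation>}, \code{<cancer>}); all other
#' tokens become lower-cased literals.  Idempotent: slot tokens pass
#' through unchanged.
#'
#' @param sentence an \code{\link{annotated_sentence}}, or a character
#'   vector already in slot form (returned as lower-cased literals with
#'   slots preserved).
#' @return character vector of tokens.
#' @export
slotify <- function(sentence) {
  if (is.character(sentence)) {
    is_slot <- sentence %in% SLOT_SYMBOLS
    return(ifelse(is_slot, sentence, tolower(sentence)))
  }
  tk <- sentence$tokens
  n <- nrow(tk)
  out <- character(0)
  covered_until <- -1L
  for (i in seq_len(n)) {
    if (tk$start[i] < covered_until) next
    hit <- NULL
    for (m in sentence$mentions) {
      if (m$start == tk$start[i]) { hit <- m; break }
    }
    if (!is.null(hit)) {
      out <- c(out, SLOT_SYMBOLS[[hit$kind]])
      covered_until <- hit$end
    } else {
      out <- c(out, tolower(tk$surface[i]))
    }
  }
  out
}

# shared token coding across sequences
encode_tokens <- function(seqs) {
  vocab <- unique(unlist(seqs, use.names = FALSE))
  lapply(seqs, function(s) match(s, vocab))
}

#' Smith-Waterman local alignment of two token sequences
#'
#' Standard local alignment with an award of +1 for a match and a
#' penalty of -1 for both mismatch and gap.  Slot symbols are ordinary
#' tokens, so a slot matches only the identical slot.  Ties in the
#' traceback prefer matches/mismatches over gaps, and the maximal cell
#' with the smallest indices, making the result deterministic.
#'
#' @param a,b character vectors of tokens.
#' @return list of class \code{sw_alignment} with \code{score},
#'   \code{a_range}/\code{b_range} (1-based inclusive token ranges of
#'   the aligned regions, \code{c(0, 0)} when the score is 0), and
#'   \code{pairs} (two-column matrix of aligned 1-based indices,
#'   \code{NA} for a gap).
#' @export
local_align <- function(a, b) {
  enc <- encode_tokens(list(as.character(a), as.character(b)))
  r <- sw_align_int(enc[[1]], enc[[2]])
  structure(
    list(score = r$score, a_range = r$a_range, b_range = r$b_range,
         pairs = cbind(a = r$pairs_a, b = r$pairs_b)),
    class = "sw_alignment"
  )
}

# stable 31-bit polynomial string hash (exact in doubles)
template_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("t%08x", as.integer(h))
}

new_template <- function(tokens, score) {
  structure(list(tokens = tokens, source_score = score,
                 identifier = template_hash(paste(tokens, collapse = " "))),
            class = "relation_template")
}

#' @export
print.relation_template <- function(x, ...) {
  cat(sprintf("<template %s score=%d> %s\n", x$identifier,
              x$source_score, paste(x$tokens, collapse = " ")))
  invisible(x)
}

# agreement subsequence of an alignment: positions aligned without gap
# where both tokens agree
agreement_tokens <- function(a, b, pairs) {
  keep <- !is.na(pairs[, 1]) & !is.na(pairs[, 2])
  pa <- pairs[keep, , drop = FALSE]
  agree <- a[pa[, 1]] == b[pa[, 2]]
  a[pa[agree, 1]]
}

#' Induce relation templates from positive sentences
#'
#' Slotifies every sentence, aligns all unordered pairs with
#' \code{\link{local_align}}, ranks pairs by alignment score descending
#' (ties by the lexicographic order of the agreement subsequence, then
#' of the pair indices), and turns each of the \code{top_k} pairs into a
#' template: the agreement subsequence of the alignment, kept when it
#' contains at least one slot symbol and at least two tokens.
#' Duplicate templates are merged, keeping the best score.  The
#' \code{review_path} export writes the candidate list as TSV for
#' optional human curation.
#'
#' @param sentences list of tagged \code{\link{annotated_sentence}}s or
#'   pre-slotified character vectors (at least 2).
#' @param top_k number of top-scoring pairs to convert (default 100).
#' @param max_sentences cap on the number of sentences aligned; larger
#'   inputs are sampled deterministically from \code{sample_seed}.
#' @param sample_seed seed for the sampling cap.
#' @param review_path optional TSV export of candidates for review.
#' @return list of \code{relation_template}, ordered by score
#'   descending.
#' @export
induce_templates <- function(sentences, top_k = 100L, max_sentences = 5000L,
                             sample_seed = 1L, review_path = NULL) {
  if (length(sentences) < 2) stop("template induction needs >= 2 sentences")
  slotted <- lapply(sentences, slotify)
  if (length(slotted) > max_sentences) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(sample_seed)
    slotted <- slotted[sort(sample.int(length(slotted), max_sentences))]
  }
  if (top_k <= 0) return(list())
  enc <- encode_tokens(slotted)
  pairs <- sw_all_pairs_int(enc, 1L)
  if (!nrow(pairs)) return(list())
  # keep enough pairs to fill top_k after tie-breaking
  ord <- order(-pairs$score)
  kth <- pairs$score[ord[min(top_k, length(ord))]]
  pairs <- pairs[pairs$score >= kth, , drop = FALSE]
  # realize alignments for the surviving pairs
  cand <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    al <- sw_align_int(enc[[i]], enc[[j]])
    toks <- agreement_tokens(slotted[[i]], slotted[[j]],
                             cbind(al$pairs_a, al$pairs_b))
    cand[[r]] <- list(score = pairs$score[r], i = i, j = j,
                      tokens = toks,
                      key = paste(toks, collapse = " "))
  }
  keys <- vapply(cand, `[[`, character(1), "key")
  scores <- vapply(cand, function(x) as.integer(x$score), integer(1))
  ii <- vapply(cand, function(x) as.integer(x$i), integer(1))
  jj <- vapply(cand, function(x) as.integer(x$j), integer(1))
  ord <- order(-scores, keys, ii, jj)
  cand <- cand[ord][seq_len(min(top_k, length(cand)))]
  if (!is.null(review_path)) {
    rev_df <- data.frame(
      score = vapply(cand, function(x) as.integer(x$score), integer(1)),
      template = vapply(cand, `[[`, character(1), "key"),
      stringsAsFactors = FALSE)
    write.table(rev_df, review_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out <- list()
  seen <- character(0)
  for (x in cand) {
    if (length(x$tokens) < 2) next
    if (!any(x$tokens %in% SLOT_SYMBOLS)) next
    if (x$key %in% seen) next
    seen <- c(seen, x$key)
    out[[length(out) + 1L]] <- new_template(x$tokens, as.integer(x$score))
  }
  out
}

# save/restore .Random.seed so induction's internal sampling does not
# disturb the caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Match a template against a slotified sentence
#'
#' True iff the template token sequence occurs contiguously in the
#' slotified sentence.
#'
#' @param template a \code{relation_template}.
#' @param sentence an \code{\link{annotated_sentence}} or slotified
#'   character vector.
#' @return logical scalar.
#' @export
match_template <- function(template, sentence) {
  s <- slotify(sentence)
  t <- template$tokens
  nt <- length(t); ns <- length(s)
  if (nt > ns) return(FALSE)
  for (i in seq_len(ns - nt + 1L)) {
    if (all(s[i:(i + nt - 1L)] == t)) return(TRUE)
  }
  FALSE
}

#' Write templates to a TSV store
#'
#' Columns: identifier, score, space-joined token sequence.  Reloading
#' with \code{\link{read_templates}} round-trips exactly.
#'
#' @param templates list of \code{relation_template}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_templates <- function(templates, path) {
  df <- data.frame(
    identifier = vapply(templates, `[[`, character(1), "identifier"),
    score = vapply(templates, function(t) as.integer(t$source_score), integer(1)),
    tokens = vapply(templates, function(t) paste(t$tokens, collapse = " "),
                    character(1)),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read templates from a TSV store
#'
#' @param path file written by \code{\link{write_templates}}.
#' @return list of \code{relation_template}.
#' @export
read_templates <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    t <- new_template(strsplit(df$tokens[i], " ", fixed = TRUE)[[1]],
                      df$score[i])
    stopifnot(t$identifier == df$identifier[i])
    t
  })
}
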