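# Rule-based shallow parsing: a regex part-of-speech guesser feeding a
# finite-state NP/VP/PP chunker.  Deliberately deterministic and
# self-contained; an external statistical chunker can be plugged in by
# supplying any function with the same signature to featurize().

DETERMINERS <- c("the", "a", "an", "this", "that", "these", "those",
                 "each", "every", "no", "its", "their", "our", "both",
                 "all", "some", "several", "many", "most")
PREPOSITIONS <- c("in", "of", "on", "for", "with", "by", "to", "from",
                  "at", "as", "than", "into", "between", "within",
                  "during", "among", "across", "through", "via",
                  "without", "after", "before", "under", "over")
AUXILIARIES <- c("is", "was", "were", "are", "am", "be", "been", "being",
                 "has", "have", "had", "do", "does", "did", "may",
                 "might", "can", "could", "shall", "should", "will",
                 "would", "must")
CONJUNCTIONS <- c("and", "or", "but", "nor", "yet")

#' Guess parts of speech with surface rules
#'
#' A small deterministic tagger sufficient to drive the shallow chunker:
#' closed-class word lists plus suffix heuristics (\code{-ed} past
#' participle, \code{-ing} gerund, \code{-ly} adverb, digits as
#' numerals); everything else defaults to noun.
#'
#' @param surfaces character vector of token surfaces.
#' @return character vector of coarse tags in
#'   \{\code{DT}, \code{IN}, \code{AUX}, \code{VB}, \code{RB},
#'   \code{CC}, \code{CD}, \code{JJ}, \code{NN}, \code{PUNCT}\}.
#' @export
guess_pos <- function(surfaces) {
  low <- tolower(surfaces)
  vapply(seq_along(surfaces), function(i) {
    s <- surfaces[i]; l <- low[i]
    if (grepl("^[[:punct:]]+$", s)) return("PUNCT")
    if (grepl("^[0-9]+([.,][0-9]+)?$", s)) return("CD")
    if (l %in% DETERMINERS) return("DT")
    if (l %in% PREPOSITIONS) return("IN")
    if (l %in% AUXILIARIES) return("AUX")
    if (l %in% CONJUNCTIONS) return("CC")
    if (l %in% c("not", "never", "also", "only")) return("RB")
    if (grepl("ly$", l) && nchar(l) > 3) return("RB")
    if (grepl("(ed|en)$", l) && nchar(l) > 4) return("VB")
    if (grepl("ing$", l) && nchar(l) > 5) return("VB")
    if (grepl("(ful|ous|ive|al|ant|ent|able|ible)$", l) && nchar(l) > 5) return("JJ")
    "NN"
  }, character(1))
}

#' Shallow-chunk a sentence
#'
#' Partitions the token sequence into NP, VP, PP and O chunks:
#' a VP is a maximal run of auxiliaries, verbs and adverbs containing at
#' least one verb (head: last verb); a PP is a preposition token (head:
#' itself); an NP is a maximal run of determiners, adjectives, numerals
#' and nouns containing a noun or numeral (head: last noun, else last
#' token); remaining tokens are singleton O chunks.
#'
#' @param sentence an \code{\link{annotated_sentence}} (or a data.frame
#'   of tokens).
#' @return data.frame with one row per chunk: \code{type},
#'   \code{from}, \code{to} (1-based token indices, inclusive),
#'   \code{head} (1-based token index), \code{head_surface}.
#' @export
chunk_sentence <- function(sentence) {
  tk <- if (is.data.frame(sentence)) sentence else sentence$tokens
  n <- nrow(tk)
  empty <- data.frame(type = character(0), from = integer(0), to = integer(0),
                      head = integer(0), head_surface = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  pos <- guess_pos(tk$surface)
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (pos[i] %in% c("AUX", "VB") ||
        (pos[i] == "RB" && i < n && pos[i + 1L] %in% c("AUX", "VB"))) {
      j <- i
      while (j < n && pos[j + 1L] %in% c("AUX", "VB", "RB")) j <- j + 1L
      verbs <- which(pos[i:j] == "VB")
      head <- if (length(verbs)) i + verbs[length(verbs)] - 1L else j
      rows[[length(rows) + 1L]] <- list("VP", i, j, head)
      i <- j + 1L
    } else if (pos[i] == "IN") {
      rows[[length(rows) + 1L]] <- list("PP", i, i, i)
      i <- i + 1L
    } else if (pos[i] %in% c("DT", "JJ", "NN", "CD")) {
      j <- i
      while (j < n && pos[j + 1L] %in% c("DT", "JJ", "NN", "CD")) j <- j + 1L
      nouns <- which(pos[i:j] == "NN")
      head <- if (length(nouns)) i + nouns[length(nouns)] - 1L else j
      rows[[length(rows) + 1L]] <- list("NP", i, j, head)
      i <- j + 1L
    } else {
      rows[[length(rows) + 1L]] <- list("O", i, i, i)
      i <- i + 1L
    }
  }
  data.frame(
    type = vapply(rows, `[[`, character(1), 1),
    from = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    to = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    head = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    head_surface = tk$surface[vapply(rows, function(r) as.integer(r[[4]]), integer(1))],
    stringsAsFactors = FALSE)
}
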