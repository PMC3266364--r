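# Sentence splitting and tokenization.  Offsets are 0-based half-open.

#' Default sentence-splitting abbreviation list
#'
#' Loads the packaged abbreviation fixture used to protect sentence-final
#' periods (\code{"et al."}, \code{"Fig."}, \code{"vs."}, ...).  Single
#' capital letters followed by a period (initials) are always protected
#' in addition to this list.
#'
#' @param path optional path to a user-supplied file (one abbreviation
#'   per line, trailing period included).
#' @return character vector of abbreviations.
#' @export
default_abbreviations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "abbreviations.txt", package = "methrelex")
  }
  x <- readLines(path, warn = FALSE)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Split text into sentence spans
#'
#' Splits on sentence-final punctuation (\code{. ! ?}) followed by
#' whitespace and an upper-case letter, digit or opening bracket, with
#' protection for known abbreviations, single-letter initials and
#' decimal numbers.  Spans cover all non-whitespace text.
#'
#' @param body the text to split.
#' @param abbreviations abbreviations whose trailing period never ends a
#'   sentence; see \code{\link{default_abbreviations}}.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open offsets into \code{body}) and \code{text}; zero rows for
#'   empty input.
#' @export
split_sentences <- function(body, abbreviations = default_abbreviations()) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (is.null(body) || !nzchar(trimws(body))) return(empty)
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # candidate breaks: terminator run, then whitespace, then U/digit/bracket
  breaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?", "\"", "'", ")")) {
        j <- j + 1L
      }
      k <- j + 1L
      while (k <= n && grepl("^\\s$", chars[k])) k <- k + 1L
      looks_like_start <- k <= n && grepl("^[A-Z0-9(\\[]$", chars[k])
      if (k > j + 1L && looks_like_start && chars[i] == ".") {
        # inspect the word carrying the period
        w <- i - 1L
        while (w >= 1L && !grepl("^\\s$", chars[w])) w <- w - 1L
        word <- paste(chars[(w + 1L):i], collapse = "")
        protected <- word %in% abbreviations ||
          grepl("^[A-Z]\\.$", word) ||              # initials "A."
          any(vapply(abbreviations, function(a) endsWith_word(body, i, a),
                     logical(1)))
        if (!protected) breaks <- c(breaks, j)
      } else if (k > j + 1L && looks_like_start) {
        breaks <- c(breaks, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  ends <- sort(unique(c(breaks, n)))
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_along(starts), function(s) {
    seg <- paste(chars[starts[s]:ends[s]], collapse = "")
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    st <- starts[s] - 1L + lead           # 0-based
    en <- ends[s] - trail
    if (en <= st) return(NULL)
    data.frame(start = st, end = en,
               text = slice0(body, st, en), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

# does the text ending at 1-based position pos end with multi-word
# abbreviation abbr ("et al.")?
endsWith_word <- function(body, pos, abbr) {
  if (!grepl(" ", abbr, fixed = TRUE)) return(FALSE)
  pre <- substr(body, max(1L, pos - nchar(abbr) + 1L), pos)
  identical(pre, abbr)
}

PUNCT_PEEL <- c(".", ",", ";", ":", "(", ")", "[", "]", "\"", "'", "%")

#' Tokenize sentence text
#'
#' Splits on whitespace, then peels leading/trailing punctuation
#' (\code{. , ; : ( ) [ ] " ' \%}) into single-character tokens.
#' Internal hyphens are kept, so \code{"hypo-methylated"} and
#' \code{"BRCA-1"} remain single tokens — required for the methylation
#' regex and gene variant lookup to work at token level.
#'
#' @param text the sentence text.
#' @return data.frame with columns \code{surface}, \code{start},
#'   \code{end} (0-based half-open offsets into \code{text}).
#' @export
tokenize <- function(text) {
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (is.null(text) || !nzchar(text)) return(empty)
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  rows <- list(); ri <- 1L
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- s + lens[i]
    raw <- slice0(text, s, e)
    # peel leading punctuation
    while (nchar(raw) > 1L && substr(raw, 1L, 1L) %in% PUNCT_PEEL) {
      rows[[ri]] <- c(substr(raw, 1L, 1L), s, s + 1L); ri <- ri + 1L
      s <- s + 1L; raw <- substr(raw, 2L, nchar(raw))
    }
    # peel trailing punctuation (collect, emit after core)
    tail_toks <- list()
    while (nchar(raw) > 1L &&
           substr(raw, nchar(raw), nchar(raw)) %in% PUNCT_PEEL) {
      tail_toks <- c(list(c(substr(raw, nchar(raw), nchar(raw)),
                            e - 1L, e)), tail_toks)
      e <- e - 1L; raw <- substr(raw, 1L, nchar(raw) - 1L)
    }
    rows[[ri]] <- c(raw, s, e); ri <- ri + 1L
    for (t in tail_toks) { rows[[ri]] <- t; ri <- ri + 1L }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("surface", "start", "end")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}
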