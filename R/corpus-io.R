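# Corpus serialization: JSON-lines standoff format, one relation
# instance per line.  Offsets on disk are 0-based half-open, matching
# the in-memory convention; the pair field stores 0-based mention
# indices.

mention_to_list <- function(m) {
  list(kind = m$kind, start = m$start, end = m$end, surface = m$surface,
       normalized_id = m$normalized_id, direction = m$direction)
}

mention_from_list <- function(x, line) {
  ok <- all(c("kind", "start", "end", "surface") %in% names(x))
  if (!ok) stop("malformed mention on line ", line, ": missing field")
  entity_mention(x$kind, x$start, x$end, x$surface,
                 normalized_id = if (is.null(x$normalized_id)) "" else x$normalized_id,
                 direction = if (is.null(x$direction)) "UNSPECIFIED" else x$direction)
}

instance_to_line <- function(inst) {
  s <- inst$sentence
  ments <- lapply(s$mentions, mention_to_list)
  idx_of <- function(e) {
    for (i in seq_along(s$mentions)) {
      m <- s$mentions[[i]]
      if (m$kind == e$kind && m$start == e$start && m$end == e$end) return(i - 1L)
    }
    stop("pair entity not found among sentence mentions")
  }
  rec <- list(
    text = s$text,
    tokens = unname(Map(function(su, st, en) list(su, st, en),
                        s$tokens$surface, s$tokens$start, s$tokens$end)),
    mentions = ments,
    relation_kind = inst$relation_kind,
    pair = c(idx_of(inst$first_entity), idx_of(inst$second_entity)),
    label = inst$label,
    probability = if (is.na(inst$probability)) NULL else inst$probability,
    sentence_index = s$sentence_index,
    sentences_in_abstract = s$sentences_in_abstract,
    document_id = if (is.na(s$document_id)) NULL else s$document_id
  )
  # digits = I(17): full IEEE double precision, so probabilities
  # round-trip bit-exactly
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17), null = "null")
}

instance_from_line <- function(line, lineno) {
  rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON on line ", lineno,
                                           ": ", conditionMessage(e)))
  req <- c("text", "tokens", "mentions", "relation_kind", "pair", "label")
  miss <- setdiff(req, names(rec))
  if (length(miss)) {
    stop("malformed record on line ", lineno, ": missing field ",
         paste(miss, collapse = ", "))
  }
  tokens <- data.frame(
    surface = vapply(rec$tokens, function(t) as.character(t[[1]]), character(1)),
    start = vapply(rec$tokens, function(t) as.integer(t[[2]]), integer(1)),
    end = vapply(rec$tokens, function(t) as.integer(t[[3]]), integer(1)),
    stringsAsFactors = FALSE)
  mentions <- lapply(seq_along(rec$mentions), function(i)
    mention_from_list(rec$mentions[[i]], lineno))
  for (m in mentions) {
    if (m$surface != slice0(rec$text, m$start, m$end)) {
      stop("validation error on line ", lineno,
           ": mention surface does not match text slice (field mentions)")
    }
  }
  sent <- annotated_sentence(
    rec$text, tokens = tokens, mentions = mentions,
    sentence_index = if (is.null(rec$sentence_index)) 0L else rec$sentence_index,
    sentences_in_abstract = if (is.null(rec$sentences_in_abstract)) 1L
                            else rec$sentences_in_abstract,
    document_id = if (is.null(rec$document_id)) NA_character_ else rec$document_id)
  pair <- vapply(rec$pair, as.integer, integer(1)) + 1L
  if (any(pair < 1L) || any(pair > length(mentions))) {
    stop("malformed record on line ", lineno, ": pair index out of range")
  }
  relation_instance(sent, rec$relation_kind,
                    mentions[[pair[1]]], mentions[[pair[2]]],
                    label = rec$label,
                    probability = if (is.null(rec$probability)) NA_real_
                                  else rec$probability)
}

#' Write a corpus to a JSON-lines standoff file
#'
#' One relation instance per line with fields \code{text},
#' \code{tokens}, \code{mentions}, \code{relation_kind}, \code{pair}
#' (0-based mention indices), \code{label}, \code{probability},
#' \code{sentence_index}, \code{sentences_in_abstract},
#' \code{document_id}.  Reading back yields a structurally identical
#' corpus.
#'
#' @param corpus a \code{\link{relation_corpus}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$instances, function(i) as.character(instance_to_line(i)),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from a JSON-lines standoff file
#'
#' @param path input file; empty files yield an empty corpus.
#' @param relation_kind expected kind; inferred from the first record
#'   when \code{NULL}.
#' @param name corpus name.
#' @return a \code{\link{relation_corpus}}.
#' @export
read_corpus <- function(path, relation_kind = NULL, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  insts <- lapply(seq_along(lines), function(i) instance_from_line(lines[i], i))
  if (is.null(relation_kind)) {
    relation_kind <- if (length(insts)) insts[[1]]$relation_kind else "GM"
  }
  relation_corpus(insts, relation_kind, name = name)
}

#' Read abstracts from JSON-lines
#'
#' Each line carries \code{pmid}, \code{title} and \code{abstract}.
#'
#' @param path JSON-lines file.
#' @return list of \code{\link{abstract_record}} (sentences not yet split).
#' @export
read_abstracts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    if (is.null(rec$pmid)) stop("malformed abstract on line ", i, ": missing pmid")
    abstract_record(as.character(rec$pmid),
                    title = if (is.null(rec$title)) "" else rec$title,
                    body = if (is.null(rec$abstract)) "" else rec$abstract)
  })
}

#' Write abstracts to JSON-lines
#'
#' @param records list of \code{\link{abstract_record}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_abstracts <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(list(pmid = r$document_id, title = r$title,
                                       abstract = r$body),
                                  auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
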