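# Core data types: entity mentions, annotated sentences, relation
# instances, corpora and abstract records.  All character offsets are
# 0-based half-open into the sentence text.

ENTITY_KINDS <- c("GENE", "METHYLATION", "CANCER")
DIRECTIONS <- c("HYPER", "HYPO", "UNSPECIFIED")
RELATION_KINDS <- c("GM", "GC")
LABELS <- c("POSITIVE", "NEGATIVE", "UNLABELED")

#' Create an entity mention
#'
#' A typed span inside a sentence.  Offsets are 0-based half-open
#' character positions into the sentence text; the stored surface must
#' equal the corresponding text slice (checked by
#' \code{\link{validate_sentence}}).
#'
#' @param kind one of \code{"GENE"}, \code{"METHYLATION"}, \code{"CANCER"}.
#' @param start,end 0-based half-open character offsets (\code{start < end}).
#' @param surface the mention text.
#' @param normalized_id identifier the mention normalizes to: an
#'   Entrez-style gene id for genes, a canonical lower-cased name for
#'   cancers, \code{""} otherwise.
#' @param direction methylation direction, one of \code{"HYPER"},
#'   \code{"HYPO"}, \code{"UNSPECIFIED"}; must be \code{"UNSPECIFIED"}
#'   for non-methylation mentions.
#' @param rule optional tag recording which NER rule produced the
#'   mention (audit trail).
#' @return an object of class \code{entity_mention}.
#' @export
entity_mention <- function(kind, start, end, surface, normalized_id = "",
                           direction = "UNSPECIFIED", rule = NA_character_) {
  kind <- match.arg(kind, ENTITY_KINDS)
  direction <- match.arg(direction, DIRECTIONS)
  if (kind != "METHYLATION" && direction != "UNSPECIFIED") {
    stop("direction must be UNSPECIFIED unless kind is METHYLATION")
  }
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop("mention start must be < end")
  structure(
    list(kind = kind, start = start, end = end, surface = surface,
         normalized_id = normalized_id, direction = direction, rule = rule),
    class = "entity_mention"
  )
}

#' Create an annotated sentence
#'
#' @param text the sentence text.
#' @param tokens data.frame with columns \code{surface}, \code{start},
#'   \code{end} (0-based half-open offsets into \code{text}); if omitted
#'   the text is tokenized with \code{\link{tokenize}}.
#' @param mentions list of \code{\link{entity_mention}} objects.
#' @param sentence_index 0-based position of the sentence in its abstract.
#' @param sentences_in_abstract total number of sentences in the abstract.
#' @param document_id identifier of the source abstract (PMID-like).
#' @return an object of class \code{annotated_sentence}.
#' @export
annotated_sentence <- function(text, tokens = NULL, mentions = list(),
                               sentence_index = 0L,
                               sentences_in_abstract = 1L,
                               document_id = NA_character_) {
  if (is.null(tokens)) tokens <- tokenize(text)
  sentence_index <- as.integer(sentence_index)
  sentences_in_abstract <- as.integer(sentences_in_abstract)
  if (sentence_index < 0L) stop("sentence_index must be >= 0")
  if (sentences_in_abstract < 1L) stop("sentences_in_abstract must be >= 1")
  if (sentence_index >= sentences_in_abstract) {
    stop("sentence_index must be < sentences_in_abstract")
  }
  s <- structure(
    list(text = text, tokens = tokens, mentions = mentions,
         sentence_index = sentence_index,
         sentences_in_abstract = sentences_in_abstract,
         document_id = document_id),
    class = "annotated_sentence"
  )
  validate_sentence(s)
  s
}

# 0-based half-open slice of a string
slice0 <- function(text, start, end) substr(text, start + 1L, end)

#' Validate an annotated sentence
#'
#' Checks token span ordering/non-overlap, mention/token boundary
#' alignment, and surface/offset consistency.  Called by constructors;
#' exported for use after manual edits.
#'
#' @param s an \code{annotated_sentence}.
#' @return \code{s}, invisibly; stops on violation.
#' @export
validate_sentence <- function(s) {
  tk <- s$tokens
  if (nrow(tk) > 0) {
    if (any(tk$start >= tk$end)) stop("token with start >= end")
    if (any(diff(tk$start) <= 0)) stop("tokens out of order")
    if (any(tk$start[-1] < tk$end[-nrow(tk)])) stop("overlapping tokens")
    bad <- which(tk$surface != mapply(slice0, tk$start, tk$end,
                                      MoreArgs = list(text = s$text)))
    if (length(bad)) stop("token surface mismatch at index ", bad[1])
  }
  boundaries_start <- tk$start
  boundaries_end <- tk$end
  for (m in s$mentions) {
    if (m$surface != slice0(s$text, m$start, m$end)) {
      stop(sprintf("mention surface %s does not equal text slice [%d,%d)",
                   dQuote(m$surface), m$start, m$end))
    }
    if (!(m$start %in% boundaries_start) || !(m$end %in% boundaries_end)) {
      stop("mention span does not align to token boundaries: ", m$surface)
    }
  }
  invisible(s)
}

#' Create a relation instance
#'
#' One sentence plus exactly one candidate entity pair: (gene,
#' methylation) for GM or (gene, cancer) for GC.  Instances are the
#' classifiers' unit of work; a multi-entity sentence is duplicated into
#' several instances by \code{\link{enumerate_pairs}}.
#'
#' @param sentence an \code{\link{annotated_sentence}} (a private copy is
#'   stored so instances share no mutable state).
#' @param relation_kind \code{"GM"} or \code{"GC"}.
#' @param first_entity,second_entity the pair; first must be a GENE,
#'   second a METHYLATION (GM) or CANCER (GC) mention from the sentence.
#' @param label \code{"POSITIVE"}, \code{"NEGATIVE"} or \code{"UNLABELED"}.
#' @param probability classifier probability of POSITIVE, or \code{NA}.
#' @return an object of class \code{relation_instance}.
#' @export
relation_instance <- function(sentence, relation_kind, first_entity,
                              second_entity, label = "UNLABELED",
                              probability = NA_real_) {
  relation_kind <- match.arg(relation_kind, RELATION_KINDS)
  label <- match.arg(label, LABELS)
  if (first_entity$kind != "GENE") stop("first entity must be a GENE")
  partner <- if (relation_kind == "GM") "METHYLATION" else "CANCER"
  if (second_entity$kind != partner) {
    stop("second entity must be a ", partner, " mention for ", relation_kind)
  }
  if (!is.na(probability) && (probability < 0 || probability > 1)) {
    stop("probability must lie in [0, 1]")
  }
  structure(
    list(sentence = sentence, relation_kind = relation_kind,
         first_entity = first_entity, second_entity = second_entity,
         label = label, probability = probability),
    class = "relation_instance"
  )
}

#' Create a relation corpus
#'
#' @param instances list of \code{\link{relation_instance}} objects, all
#'   sharing \code{relation_kind}.
#' @param relation_kind \code{"GM"} or \code{"GC"}.
#' @param name corpus name.
#' @return an object of class \code{relation_corpus}.
#' @export
relation_corpus <- function(instances, relation_kind, name = "corpus") {
  relation_kind <- match.arg(relation_kind, RELATION_KINDS)
  kinds <- vapply(instances, function(x) x$relation_kind, character(1))
  if (length(kinds) && any(kinds != relation_kind)) {
    stop("all instances must share the corpus relation_kind")
  }
  structure(list(name = name, instances = instances,
                 relation_kind = relation_kind),
            class = "relation_corpus")
}

#' @export
print.relation_corpus <- function(x, ...) {
  labs <- corpus_labels(x)
  cat(sprintf("<relation_corpus '%s'> kind=%s n=%d (%d positive, %d negative, %d unlabeled)\n",
              x$name, x$relation_kind, length(x$instances),
              sum(labs == "POSITIVE"), sum(labs == "NEGATIVE"),
              sum(labs == "UNLABELED")))
  invisible(x)
}

#' Labels of all instances in a corpus
#' @param corpus a \code{relation_corpus}.
#' @return character vector of labels.
#' @export
corpus_labels <- function(corpus) {
  vapply(corpus$instances, function(x) x$label, character(1))
}

#' Create an abstract record
#'
#' @param document_id PMID-like identifier.
#' @param title abstract title (may be empty; when non-empty it is
#'   treated as sentence 0 by \code{\link{annotate_abstract}}).
#' @param body abstract body text.
#' @param sentences list of \code{\link{annotated_sentence}} objects in
#'   document order.
#' @return an object of class \code{abstract_record}.
#' @export
abstract_record <- function(document_id, title = "", body = "",
                            sentences = list()) {
  structure(list(document_id = document_id, title = title, body = body,
                 sentences = sentences),
            class = "abstract_record")
}

#' Split an abstract into annotated sentences
#'
#' Runs sentence splitting and tokenization over the title (when
#' non-empty, as sentence 0) and body of an abstract, filling in
#' \code{sentence_index} and \code{sentences_in_abstract}.
#'
#' @param record an \code{\link{abstract_record}} (sentences ignored).
#' @param abbreviations abbreviation list passed to
#'   \code{\link{split_sentences}}.
#' @return the record with \code{sentences} populated.
#' @export
annotate_abstract <- function(record, abbreviations = default_abbreviations()) {
  texts <- character(0)
  if (nzchar(record$title)) texts <- record$title
  if (nzchar(record$body)) {
    spans <- split_sentences(record$body, abbreviations)
    texts <- c(texts, spans$text)
  }
  n <- length(texts)
  record$sentences <- lapply(seq_along(texts), function(i) {
    annotated_sentence(texts[i], sentence_index = i - 1L,
                       sentences_in_abstract = max(n, 1L),
                       document_id = record$document_id)
  })
  record
}

#' Enumerate candidate relation pairs in a sentence
#'
#' Duplicates a sentence into one \code{\link{relation_instance}} per
#' (gene, partner) combination: the Cartesian product of GENE mentions
#' with METHYLATION (GM) or CANCER (GC) mentions.  Each instance carries
#' its own copy of the sentence so downstream feature extraction cannot
#' leak state across pairs.
#'
#' @param sentence an annotated sentence with mentions tagged.
#' @param relation_kind \code{"GM"} or \code{"GC"}.
#' @param genes optional subset of GENE mentions to pair (defaults to all
#'   GENE mentions in the sentence); used by the staged pipeline to
#'   restrict the GC stage to positively-methylated genes.
#' @return list of \code{relation_instance} with label
#'   \code{"UNLABELED"}; empty when either side of the product is empty.
#' @export
enumerate_pairs <- function(sentence, relation_kind, genes = NULL) {
  relation_kind <- match.arg(relation_kind, RELATION_KINDS)
  partner_kind <- if (relation_kind == "GM") "METHYLATION" else "CANCER"
  kinds <- vapply(sentence$mentions, function(m) m$kind, character(1))
  if (is.null(genes)) genes <- sentence$mentions[kinds == "GENE"]
  partners <- sentence$mentions[kinds == partner_kind]
  if (!length(genes) || !length(partners)) return(list())
  out <- vector("list", length(genes) * length(partners))
  k <- 1L
  for (g in genes) {
    for (p in partners) {
      out[[k]] <- relation_instance(sentence, relation_kind, g, p)
      k <- k + 1L
    }
  }
  out
}
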