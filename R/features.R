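# Binary feature extraction for relation instances: inter-entity word
# n-grams, surrounding words, shallow-chunk features, a parse-path
# feature (chunk-sequence fallback by default), sentence position, and
# template matches.  Every feature is a name; a vector is the set of
# names present.

BOUNDARY_TOKEN <- "<S>"

#' Feature extraction configuration
#'
#' @param lowercase lower-case lexical features.
#' @param num_placeholder map numeral tokens to \code{#NUM} to limit
#'   sparsity.
#' @param groups feature groups to emit; removing a group removes
#'   exactly those features (ablation harness).
#' @return a list of class \code{feature_config}.
#' @export
feature_config <- function(lowercase = TRUE, num_placeholder = TRUE,
                           groups = c("NGRAM1", "NGRAM2", "SURROUND_LEFT",
                                      "SURROUND_RIGHT", "CHUNK_HEAD_INTER",
                                      "CHUNK_HEAD_SURROUND",
                                      "CHUNK_TYPE_INTER", "PARSE_PATH",
                                      "SENT_POS", "TEMPLATE", "ORDER")) {
  structure(list(lowercase = lowercase, num_placeholder = num_placeholder,
                 groups = groups),
            class = "feature_config")
}

norm_word <- function(w, config) {
  if (config$num_placeholder && grepl("^[0-9]+([.,][0-9]+)?$", w)) return("#NUM")
  if (config$lowercase) tolower(w) else w
}

# token index ranges of the two pair entities, in document order
entity_token_spans <- function(instance) {
  tk <- instance$sentence$tokens
  span <- function(e) {
    idx <- which(tk$start >= e$start & tk$end <= e$end)
    if (!length(idx)) stop("entity does not align to tokens")
    range(idx)
  }
  a <- span(instance$first_entity)
  b <- span(instance$second_entity)
  if (a[1] <= b[1]) list(first = a, second = b, gene_first = TRUE)
  else list(first = b, second = a, gene_first = FALSE)
}

#' Inter-entity word n-gram features
#'
#' One \code{NGRAM1} feature per token strictly between the two entity
#' spans (document order) and one \code{NGRAM2} feature per adjacent
#' token pair between them.
#'
#' @param instance a \code{\link{relation_instance}}.
#' @param config a \code{\link{feature_config}}.
#' @return character vector of feature names.
#' @export
ngram_features <- function(instance, config = feature_config()) {
  sp <- entity_token_spans(instance)
  tk <- instance$sentence$tokens
  lo <- sp$first[2] + 1L; hi <- sp$second[1] - 1L
  if (lo > hi) return(character(0))
  words <- vapply(tk$surface[lo:hi], norm_word, character(1),
                  config = config, USE.NAMES = FALSE)
  out <- character(0)
  if ("NGRAM1" %in% config$groups) out <- c(out, paste0("NGRAM1=", words))
  if ("NGRAM2" %in% config$groups && length(words) > 1) {
    out <- c(out, paste0("NGRAM2=", head(words, -1), "_", words[-1]))
  }
  unique(out)
}

#' Surrounding word features
#'
#' The two words before the first entity (positions -2, -1 in document
#' order) and the two after the second (+1, +2); positions beyond the
#' sentence bounds emit the boundary marker \code{<S>}.
#'
#' @inheritParams ngram_features
#' @return character vector of feature names.
#' @export
surrounding_word_features <- function(instance, config = feature_config()) {
  sp <- entity_token_spans(instance)
  tk <- instance$sentence$tokens
  n <- nrow(tk)
  word_at <- function(i) {
    if (i < 1L || i > n) BOUNDARY_TOKEN else norm_word(tk$surface[i], config)
  }
  out <- character(0)
  if ("SURROUND_LEFT" %in% config$groups) {
    out <- c(out,
             paste0("SURROUND_L2=", word_at(sp$first[1] - 2L)),
             paste0("SURROUND_L1=", word_at(sp$first[1] - 1L)))
  }
  if ("SURROUND_RIGHT" %in% config$groups) {
    out <- c(out,
             paste0("SURROUND_R1=", word_at(sp$second[2] + 1L)),
             paste0("SURROUND_R2=", word_at(sp$second[2] + 2L)))
  }
  out
}

#' Chunk features
#'
#' \code{CHUNK_HEAD_INTER} for each chunk head strictly between the
#' entities' chunks, \code{CHUNK_TYPE_INTER} as the concatenated type
#' sequence of those chunks, and \code{CHUNK_HEAD_SURROUND} for the
#' chunk immediately before the first entity and after the second.
#'
#' @inheritParams ngram_features
#' @param chunks chunk table from \code{\link{chunk_sentence}}; computed
#'   when \code{NULL}.
#' @return character vector of feature names.
#' @export
chunk_features <- function(instance, chunks = NULL,
                           config = feature_config()) {
  if (is.null(chunks)) chunks <- chunk_sentence(instance$sentence)
  sp <- entity_token_spans(instance)
  chunk_of <- function(tok) which(chunks$from <= tok & chunks$to >= tok)[1]
  c1 <- chunk_of(sp$first[2]); c2 <- chunk_of(sp$second[1])
  inter <- if (c1 + 1L <= c2 - 1L) seq(c1 + 1L, c2 - 1L) else integer(0)
  out <- character(0)
  if ("CHUNK_HEAD_INTER" %in% config$groups && length(inter)) {
    heads <- vapply(chunks$head_surface[inter], norm_word, character(1),
                    config = config, USE.NAMES = FALSE)
    out <- c(out, unique(paste0("CHUNK_HEAD_INTER=", heads)))
  }
  if ("CHUNK_TYPE_INTER" %in% config$groups) {
    out <- c(out, paste0("CHUNK_TYPE_INTER=",
                         paste(chunks$type[inter], collapse = "_")))
  }
  if ("CHUNK_HEAD_SURROUND" %in% config$groups) {
    before <- chunk_of(sp$first[1]) - 1L
    after <- chunk_of(sp$second[2]) + 1L
    left <- if (before >= 1L) norm_word(chunks$head_surface[before], config)
            else BOUNDARY_TOKEN
    right <- if (after <= nrow(chunks)) norm_word(chunks$head_surface[after], config)
             else BOUNDARY_TOKEN
    out <- c(out, paste0("CHUNK_HEAD_SURROUND_L=", left),
             paste0("CHUNK_HEAD_SURROUND_R=", right))
  }
  out
}

#' Parse-path feature
#'
#' Encodes the syntactic path between the two entities.  With the
#' default shallow pipeline no constituency parse is available and the
#' fallback path is used: the chunk-type sequence between the entities,
#' prefixed \code{FALLBACK:}.  A full parser adapter may be supplied as
#' a function \code{parser(sentence, span1, span2)} returning a path
#' string such as \code{"NP^S_VP"}.
#'
#' @inheritParams chunk_features
#' @param parser optional parser adapter; on error the fallback path is
#'   used.
#' @return character vector with one \code{PARSE_PATH} feature.
#' @export
parse_path_feature <- function(instance, chunks = NULL, parser = NULL,
                               config = feature_config()) {
  if (!"PARSE_PATH" %in% config$groups) return(character(0))
  if (is.null(chunks)) chunks <- chunk_sentence(instance$sentence)
  sp <- entity_token_spans(instance)
  if (!is.null(parser)) {
    path <- tryCatch(parser(instance$sentence, sp$first, sp$second),
                     error = function(e) NULL)
    if (!is.null(path)) return(paste0("PARSE_PATH=", path))
  }
  chunk_of <- function(tok) which(chunks$from <= tok & chunks$to >= tok)[1]
  c1 <- chunk_of(sp$first[2]); c2 <- chunk_of(sp$second[1])
  inter <- if (c1 + 1L <= c2 - 1L) seq(c1 + 1L, c2 - 1L) else integer(0)
  paste0("PARSE_PATH=FALLBACK:", paste(chunks$type[inter], collapse = "_"))
}

#' Sentence-position feature
#'
#' Relative position r = sentence_index / (total - 1) (r = 0 for a
#' single-sentence abstract), discretized into quintile buckets Q1..Q5.
#'
#' @inheritParams ngram_features
#' @return character vector with one \code{SENT_POS} feature.
#' @export
sentence_position_feature <- function(instance, config = feature_config()) {
  if (!"SENT_POS" %in% config$groups) return(character(0))
  s <- instance$sentence
  total <- s$sentences_in_abstract
  r <- if (total <= 1L) 0 else s$sentence_index / (total - 1)
  bucket <- min(5L, floor(r * 5) + 1L)
  paste0("SENT_POS=Q", bucket)
}

#' Template-match features
#'
#' One \code{TEMPLATE} feature per induced template whose token sequence
#' occurs contiguously in the slotified sentence.
#'
#' @inheritParams ngram_features
#' @param templates list of \code{\link{induce_templates}} output.
#' @return character vector of feature names.
#' @export
template_features <- function(instance, templates,
                              config = feature_config()) {
  if (!"TEMPLATE" %in% config$groups || !length(templates)) return(character(0))
  slots <- slotify(instance$sentence)
  hits <- vapply(templates, function(tp) match_template(tp, slots), logical(1))
  if (!any(hits)) return(character(0))
  paste0("TEMPLATE=", vapply(templates[hits], function(tp) tp$identifier,
                             character(1)))
}

#' Extract the full feature vector of an instance
#'
#' Union of all configured feature groups.  Extraction is pure: the same
#' instance with the same annotators always yields the identical set.
#' An \code{ORDER} feature records whether the gene precedes its partner
#' in the sentence.
#'
#' @inheritParams chunk_features
#' @param templates optional template list for \code{TEMPLATE} features.
#' @param parser optional parser adapter for \code{PARSE_PATH}.
#' @return character vector of feature names (a set).
#' @export
featurize <- function(instance, templates = NULL, chunks = NULL,
                      parser = NULL, config = feature_config()) {
  if (is.null(chunks)) chunks <- chunk_sentence(instance$sentence)
  sp <- entity_token_spans(instance)
  out <- c(
    ngram_features(instance, config),
    surrounding_word_features(instance, config),
    chunk_features(instance, chunks, config),
    parse_path_feature(instance, chunks, parser, config),
    sentence_position_feature(instance, config),
    template_features(instance, templates, config)
  )
  if ("ORDER" %in% config$groups) {
    out <- c(out, paste0("ORDER=", if (sp$gene_first) "GENE_FIRST" else "GENE_SECOND"))
  }
  unique(out)
}

#' Featurize a corpus
#'
#' @param corpus a \code{\link{relation_corpus}}.
#' @inheritParams featurize
#' @return list with \code{features} (list of character vectors),
#'   \code{labels} (character), \code{groups} (per-instance source
#'   sentence key used to keep duplicated instances in one CV fold).
#' @export
featurize_corpus <- function(corpus, templates = NULL, parser = NULL,
                             config = feature_config()) {
  feats <- lapply(corpus$instances, featurize, templates = templates,
                  parser = parser, config = config)
  groups <- vapply(corpus$instances, function(i) {
    s <- i$sentence
    paste0(ifelse(is.na(s$document_id), "?", s$document_id), "#",
           s$sentence_index, "#", substr(s$text, 1, 40))
  }, character(1))
  list(features = feats, labels = corpus_labels(corpus), groups = groups)
}

#' Write feature vectors in sparse text format
#'
#' Classic maxent toolkit input: one instance per line,
#' \code{label feat:1 feat:1 ...}.
#'
#' @param features list of character vectors.
#' @param labels character vector of labels.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sparse_features <- function(features, labels, path) {
  lines <- vapply(seq_along(features), function(i) {
    paste(c(labels[i], paste0(features[[i]], ":1")), collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read sparse text feature vectors
#'
#' @param path file written by \code{\link{write_sparse_features}}.
#' @return list with \code{features} and \code{labels}.
#' @export
read_sparse_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  labels <- character(length(lines))
  features <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    features[[i]] <- sub(":1$", "", parts[-1])
  }
  list(features = features, labels = labels)
}
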