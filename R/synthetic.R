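# Synthetic annotated corpora with controllable relational signal.
# Sentences are assembled from frame families: cue frames that state a
# relation (or its negation / a non-relational co-occurrence) and
# neutral frames used verbatim by both classes, so signal_strength
# controls how separable the corpus is by construction.  Everything is
# deterministic given the seed.

DEFAULT_GENES <- c("MGMT", "BRCA1", "GSTP1", "ESR1", "CDKN2A", "CDKN2B",
                   "MLH1", "DAPK1", "CDH1", "TIMP3", "TP73", "APC",
                   "SOCS1", "SOCS2", "SOCS3", "RASSF1", "RARB", "PYCARD",
                   "GATA4", "SYK", "PRDM2", "PGR", "SFRP1", "STK11",
                   "TMEFF2", "THBS1", "VHL", "RB1", "HIC1", "CCND2")

DEFAULT_CANCERS <- c("breast cancer", "lung cancer", "gastric cancer",
                     "colorectal cancer", "ovarian cancer",
                     "prostate cancer", "bladder cancer", "melanoma",
                     "glioma", "leukemia", "hepatocellular carcinoma",
                     "nasopharyngeal carcinoma")

#' Synthetic-corpus generator configuration
#'
#' @param seed RNG seed; the whole generation is deterministic given it.
#' @param n_abstracts,sentences_per_abstract corpus volume when no exact
#'   instance quota is requested; sentences are grouped into abstracts
#'   of this size for the sentence-position feature and end-to-end runs.
#' @param gene_vocabulary,cancer_vocabulary non-empty surface
#'   vocabularies; defaults are drawn from the packaged dictionaries so
#'   generated text round-trips through the taggers.
#' @param positive_fraction fraction of positive instances.
#' @param signal_strength probability that a positive (or cue-negative)
#'   instance uses a class-specific cue frame rather than a neutral
#'   frame shared by both classes; 1 makes the corpus separable by
#'   construction.
#' @param negation_fraction fraction of cue negatives realized as
#'   explicit negations rather than non-relational co-occurrences.
#' @param multi_entity_rate expected number of extra genes per sentence
#'   (Poisson); multi-gene sentences expand into several single-pair
#'   instances sharing the sentence's label.
#' @return a list of class \code{generator_config}.
#' @export
generator_config <- function(seed = 1L, n_abstracts = 250L,
                             sentences_per_abstract = 8L,
                             gene_vocabulary = DEFAULT_GENES,
                             cancer_vocabulary = DEFAULT_CANCERS,
                             positive_fraction = 0.5,
                             signal_strength = 0.9,
                             negation_fraction = 0.3,
                             multi_entity_rate = 0.5) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1,
            signal_strength >= 0, signal_strength <= 1,
            negation_fraction >= 0, negation_fraction <= 1,
            multi_entity_rate >= 0)
  if (!length(gene_vocabulary) || !length(cancer_vocabulary)) {
    stop("vocabularies must be non-empty")
  }
  structure(list(seed = as.integer(seed), n_abstracts = as.integer(n_abstracts),
                 sentences_per_abstract = as.integer(sentences_per_abstract),
                 gene_vocabulary = gene_vocabulary,
                 cancer_vocabulary = cancer_vocabulary,
                 positive_fraction = positive_fraction,
                 signal_strength = signal_strength,
                 negation_fraction = negation_fraction,
                 multi_entity_rate = multi_entity_rate),
            class = "generator_config")
}

# ---- sentence assembly -------------------------------------------------

# parts: list of elements list(kind = "lit"/"gene"/"meth"/"cancer", ...)
assemble_sentence <- function(parts, sentence_index, total, document_id) {
  tokens <- character(0)
  mention_spec <- list()   # (kind, from, to, id, direction)
  for (p in parts) {
    from <- length(tokens) + 1L
    if (p$kind == "lit") {
      tokens <- c(tokens, p$tokens)
    } else if (p$kind == "gene") {
      tokens <- c(tokens, p$symbol)
      mention_spec[[length(mention_spec) + 1L]] <-
        list(kind = "GENE", from = from, to = from, id = p$symbol,
             direction = "UNSPECIFIED")
    } else if (p$kind == "meth") {
      tokens <- c(tokens, p$surface)
      mention_spec[[length(mention_spec) + 1L]] <-
        list(kind = "METHYLATION", from = from, to = from, id = "",
             direction = p$direction)
    } else if (p$kind == "cancer") {
      ct <- strsplit(p$name, " ", fixed = TRUE)[[1]]
      tokens <- c(tokens, ct)
      mention_spec[[length(mention_spec) + 1L]] <-
        list(kind = "CANCER", from = from, to = from + length(ct) - 1L,
             id = p$name, direction = "UNSPECIFIED")
    }
  }
  starts <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  ends <- starts + nchar(tokens)
  text <- paste(tokens, collapse = " ")
  tk <- data.frame(surface = tokens, start = starts, end = ends,
                   stringsAsFactors = FALSE)
  mentions <- lapply(mention_spec, function(m) {
    entity_mention(m$kind, starts[m$from], ends[m$to],
                   slice0(text, starts[m$from], ends[m$to]),
                   normalized_id = m$id, direction = m$direction,
                   rule = "gold")
  })
  annotated_sentence(text, tokens = tk, mentions = mentions,
                     sentence_index = sentence_index,
                     sentences_in_abstract = total,
                     document_id = document_id)
}

lit <- function(...) list(kind = "lit", tokens = c(...))
gene_part <- function(symbol) list(kind = "gene", symbol = symbol)
meth_part <- function(surface) {
  dir <- if (startsWith(surface, "hyper")) "HYPER"
         else if (startsWith(surface, "hypo")) "HYPO" else "UNSPECIFIED"
  list(kind = "meth", surface = surface, direction = dir)
}
cancer_part <- function(name) list(kind = "cancer", name = name)

# "G1 , G2 , and G3" as parts
gene_list_parts <- function(genes) {
  n <- length(genes)
  parts <- list()
  for (i in seq_len(n)) {
    if (i > 1) {
      parts[[length(parts) + 1L]] <-
        if (i == n) lit(",", "and") else lit(",")
    }
    parts[[length(parts) + 1L]] <- gene_part(genes[i])
  }
  parts
}

meth_surface <- function(u, participle) {
  base <- if (participle) "methylated" else "methylation"
  if (u < 0.4) paste0("hyper", base) else if (u < 0.6) paste0("hypo", base)
  else base
}

# frame builders return the parts list; u* are uniforms already drawn
positive_frame <- function(which, genes, cancer, msurf_p, msurf_n, pct) {
  copula <- if (length(genes) > 1) "were" else "was"
  be <- if (length(genes) > 1) "are" else "is"
  switch(which,
    c(gene_list_parts(genes), list(lit(copula), meth_part(msurf_p),
      lit("in"), lit(pct), lit("%"), lit("of")), list(cancer_part(cancer)),
      list(lit("samples"), lit(","), lit("respectively"), lit("."))),
    c(gene_list_parts(genes), list(lit("promoter"), meth_part(msurf_n),
      lit(copula), lit("detected"), lit("in")), list(cancer_part(cancer)),
      list(lit("."))),
    c(gene_list_parts(genes), list(lit(be), lit("frequently"),
      meth_part("methylated"), lit("in")), list(cancer_part(cancer)),
      list(lit("."))),
    c(list(lit("aberrant"), meth_part(msurf_n), lit("of")),
      gene_list_parts(genes),
      list(lit(copula), lit("observed"), lit("in")),
      list(cancer_part(cancer)), list(lit("tissues"), lit(".")))
  )
}

negated_frame <- function(which, genes, cancer, msurf_n) {
  copula <- if (length(genes) > 1) "were" else "was"
  switch(which,
    c(gene_list_parts(genes), list(lit(copula), lit("not"),
      meth_part("methylated"), lit("in")), list(cancer_part(cancer)),
      list(lit("samples"), lit("."))),
    c(list(lit("no"), meth_part(msurf_n), lit("of")),
      gene_list_parts(genes),
      list(lit(copula), lit("detected"), lit("in")),
      list(cancer_part(cancer)), list(lit("cells"), lit(".")))
  )
}

nonrel_frame <- function(which, genes, cancer, msurf_n) {
  switch(which,
    c(list(lit("the"), meth_part(msurf_n), lit("assay"), lit("was"),
      lit("calibrated"), lit(","), lit("while")), gene_list_parts(genes),
      list(lit("expression"), lit("was"), lit("measured"), lit("in")),
      list(cancer_part(cancer)), list(lit("tissues"), lit("."))),
    c(list(lit("expression"), lit("of")), gene_list_parts(genes),
      list(lit(","), lit("rather"), lit("than"), meth_part(msurf_n),
      lit(","), lit("correlated"), lit("with")),
      list(cancer_part(cancer)), list(lit("progression"), lit(".")))
  )
}

gc_negative_frame <- function(which, genes, cancer, msurf_n) {
  copula <- if (length(genes) > 1) "were" else "was"
  switch(which,
    c(gene_list_parts(genes), list(lit(copula), meth_part("methylated"),
      lit("in"), lit("normal"), lit("tissue"), lit("but"), lit("showed"),
      lit("no"), lit("association"), lit("with")),
      list(cancer_part(cancer)), list(lit("."))),
    c(gene_list_parts(genes), list(meth_part(msurf_n), lit("was"),
      lit("unrelated"), lit("to")), list(cancer_part(cancer)),
      list(lit("risk"), lit(".")))
  )
}

neutral_frame <- function(which, genes, cancer, msurf_n) {
  switch(which,
    c(list(lit("the"), meth_part(msurf_n), lit("profile"), lit("of")),
      gene_list_parts(genes), list(lit("in")), list(cancer_part(cancer)),
      list(lit("was"), lit("investigated"), lit("."))),
    c(list(lit("we"), lit("examined"), meth_part(msurf_n), lit("of")),
      gene_list_parts(genes), list(lit("in")), list(cancer_part(cancer)),
      list(lit("samples"), lit("."))),
    c(gene_list_parts(genes), list(meth_part(msurf_n), lit("in")),
      list(cancer_part(cancer)), list(lit("has"), lit("been"),
      lit("studied"), lit("previously"), lit(".")))
  )
}

# draw one sentence; returns list(sentence, label, n_genes)
draw_sentence <- function(config, relation_kind, label, n_genes,
                          sentence_index, total, document_id) {
  genes <- sample(config$gene_vocabulary, n_genes)
  cancer <- sample(config$cancer_vocabulary, 1L)
  msurf_p <- meth_surface(runif(1), participle = TRUE)
  msurf_n <- meth_surface(runif(1), participle = FALSE)
  pct <- as.character(sample(5:95, 1L))
  use_cue <- runif(1) < config$signal_strength
  parts <- if (!use_cue) {
    neutral_frame(sample.int(3, 1), genes, cancer, msurf_n)
  } else if (label == "POSITIVE") {
    positive_frame(sample.int(4, 1), genes, cancer, msurf_p, msurf_n, pct)
  } else if (relation_kind == "GC" && runif(1) < 0.5) {
    gc_negative_frame(sample.int(2, 1), genes, cancer, msurf_n)
  } else if (runif(1) < config$negation_fraction) {
    negated_frame(sample.int(2, 1), genes, cancer, msurf_n)
  } else {
    nonrel_frame(sample.int(2, 1), genes, cancer, msurf_n)
  }
  assemble_sentence(parts, sentence_index, total, document_id)
}

sentence_instances <- function(sentence, relation_kind, label) {
  pairs <- enumerate_pairs(sentence, relation_kind)
  lapply(pairs, function(p) { p$label <- label; p })
}

#' Generate synthetic G-M and G-C corpora with gold labels
#'
#' Draws labeled sentences frame-by-frame (see
#' \code{\link{generator_config}}), expands multi-gene sentences into
#' single-pair instances that share the sentence label, and groups all
#' generated sentences into abstracts.  With \code{n_instances} set,
#' each corpus contains exactly that many instances with the positive
#' count \code{round(n_instances * positive_fraction)}; otherwise the
#' volume follows \code{n_abstracts * sentences_per_abstract} sentences
#' per corpus.
#'
#' @param config a \code{\link{generator_config}}.
#' @param n_instances optional exact instance count per corpus.
#' @return list with \code{gm} and \code{gc}
#'   (\code{\link{relation_corpus}}) and \code{abstracts} (list of
#'   \code{\link{abstract_record}}).
#' @export
generate_corpus <- function(config, n_instances = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  spa <- config$sentences_per_abstract
  sent_counter <- 0L
  all_sentences <- list()
  next_position <- function() {
    idx <- sent_counter %% spa
    doc <- sprintf("SYN%05d", sent_counter %/% spa + 1L)
    sent_counter <<- sent_counter + 1L
    list(index = idx, doc = doc)
  }
  gen_stream <- function(relation_kind) {
    insts <- list()
    if (is.null(n_instances)) {
      n_sent <- config$n_abstracts * spa
      for (s in seq_len(n_sent)) {
        label <- if (runif(1) < config$positive_fraction) "POSITIVE" else "NEGATIVE"
        n_genes <- min(1L + rpois(1, config$multi_entity_rate),
                       length(config$gene_vocabulary))
        pos <- next_position()
        sent <- draw_sentence(config, relation_kind, label, n_genes,
                              pos$index, spa, pos$doc)
        all_sentences[[length(all_sentences) + 1L]] <<- sent
        insts <- c(insts, sentence_instances(sent, relation_kind, label))
      }
    } else {
      quota <- c(POSITIVE = round(n_instances * config$positive_fraction))
      quota <- c(quota, NEGATIVE = n_instances - unname(quota))
      if (max(quota) > 0 && length(config$gene_vocabulary) < 1) {
        stop("gene vocabulary exhausted")
      }
      while (sum(quota) > 0) {
        label <- sample(names(quota), 1L, prob = quota / sum(quota))
        n_genes <- min(1L + rpois(1, config$multi_entity_rate),
                       quota[[label]], length(config$gene_vocabulary))
        pos <- next_position()
        sent <- draw_sentence(config, relation_kind, label, n_genes,
                              pos$index, spa, pos$doc)
        all_sentences[[length(all_sentences) + 1L]] <<- sent
        insts <- c(insts, sentence_instances(sent, relation_kind, label))
        quota[[label]] <- quota[[label]] - n_genes
      }
    }
    insts
  }
  gm <- relation_corpus(gen_stream("GM"), "GM", name = "synthetic-GM")
  gc <- relation_corpus(gen_stream("GC"), "GC", name = "synthetic-GC")
  # group sentences into abstract records
  docs <- split(all_sentences,
                vapply(all_sentences, function(s) s$document_id, character(1)))
  abstracts <- lapply(names(docs), function(d) {
    sents <- docs[[d]]
    ord <- order(vapply(sents, function(s) s$sentence_index, integer(1)))
    sents <- sents[ord]
    body <- paste(vapply(sents, function(s) s$text, character(1)),
                  collapse = " ")
    abstract_record(d, title = "", body = body, sentences = sents)
  })
  abstracts <- abstracts[order(vapply(abstracts, function(a) a$document_id,
                                      character(1)))]
  list(gm = gm, gc = gc, abstracts = abstracts)
}
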