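# Staged extraction and evidence ranking.  Stage 1 classifies
# gene-methylation pairs; sentences with at least one positive G-M pair
# are cancer-tagged and the positively-methylated genes are paired with
# cancer mentions for stage 2.  Positive G-C instances become evidence
# sentences; evidence is aggregated per (gene, cancer) with the ranking
# score = sum of the G-C positive probabilities over evidence sentences.

#' Run the staged relation extraction pipeline
#'
#' For each sentence of each abstract: tag methylation terms and genes,
#' enumerate and classify G-M pairs; for sentences with at least one
#' POSITIVE G-M pair, tag cancers, pair the positively-methylated genes
#' with each cancer mention, classify the G-C pairs, and emit one
#' evidence row per POSITIVE G-C instance carrying both stage
#' probabilities and the methylation direction of the gene's best G-M
#' pair.
#'
#' @param abstracts list of \code{\link{abstract_record}}; records
#'   without sentences are split with \code{\link{annotate_abstract}}.
#' @param gm_model,gc_model trained \code{\link{maxent_model}}s (or any
#'   function \code{f(features) -> probability} for oracle testing).
#' @param gene_lex a \code{\link{gene_lexicon}}.
#' @param cancer_lex a \code{\link{cancer_lexicon}}.
#' @param templates optional template list for TEMPLATE features.
#' @param config a \code{\link{feature_config}}.
#' @param threshold POSITIVE decision threshold for both stages.
#' @param verbose log per-stage counts.
#' @return data.frame of evidence sentences with columns
#'   \code{document_id}, \code{sentence_index}, \code{text},
#'   \code{gene_id}, \code{gene_surface}, \code{cancer_name},
#'   \code{gm_probability}, \code{gc_probability}, \code{direction}.
#' @export
extract_evidence <- function(abstracts, gm_model, gc_model,
                             gene_lex = gene_lexicon(),
                             cancer_lex = cancer_lexicon(),
                             templates = NULL,
                             config = feature_config(),
                             threshold = 0.5, verbose = FALSE) {
  prob_of <- function(model, feats) {
    if (is.function(model)) vapply(feats, model, numeric(1))
    else predict_maxent(model, feats)
  }
  if (!is.function(gm_model) && !inherits(gm_model, "maxent_model")) {
    stop("gm_model must be a trained maxent_model or a function")
  }
  if (!is.function(gc_model) && !inherits(gc_model, "maxent_model")) {
    stop("gc_model must be a trained maxent_model or a function")
  }
  rows <- list()
  stats <- c(sentences = 0L, gm_pairs = 0L, gm_positive = 0L,
             gc_pairs = 0L, gc_positive = 0L)
  for (rec in abstracts) {
    if (!length(rec$sentences)) rec <- annotate_abstract(rec)
    for (sent in rec$sentences) {
      stats["sentences"] <- stats["sentences"] + 1L
      sent <- tag_methylation(sent)
      sent <- tag_genes(sent, gene_lex)
      gm_pairs <- enumerate_pairs(sent, "GM")
      if (!length(gm_pairs)) next
      stats["gm_pairs"] <- stats["gm_pairs"] + length(gm_pairs)
      gm_feats <- lapply(gm_pairs, featurize, templates = templates,
                         config = config)
      gm_probs <- prob_of(gm_model, gm_feats)
      pos <- which(gm_probs >= threshold)
      if (!length(pos)) next
      stats["gm_positive"] <- stats["gm_positive"] + length(pos)
      # best positive G-M pair per gene: probability and direction
      gene_best <- list()
      for (i in pos) {
        g <- gm_pairs[[i]]$first_entity
        key <- g$normalized_id
        prev <- gene_best[[key]]
        if (is.null(prev) || gm_probs[i] > prev$prob) {
          gene_best[[key]] <- list(
            mention = g, prob = gm_probs[i],
            direction = gm_pairs[[i]]$second_entity$direction)
        }
      }
      sent_c <- tag_cancer(sent, cancer_lex)
      pos_genes <- lapply(gene_best, `[[`, "mention")
      gc_pairs <- enumerate_pairs(sent_c, "GC", genes = unname(pos_genes))
      if (!length(gc_pairs)) next
      stats["gc_pairs"] <- stats["gc_pairs"] + length(gc_pairs)
      gc_feats <- lapply(gc_pairs, featurize, templates = templates,
                         config = config)
      gc_probs <- prob_of(gc_model, gc_feats)
      for (i in which(gc_probs >= threshold)) {
        stats["gc_positive"] <- stats["gc_positive"] + 1L
        inst <- gc_pairs[[i]]
        gkey <- inst$first_entity$normalized_id
        rows[[length(rows) + 1L]] <- data.frame(
          document_id = if (is.na(sent$document_id)) "" else sent$document_id,
          sentence_index = sent$sentence_index,
          text = sent$text,
          gene_id = gkey,
          gene_surface = inst$first_entity$surface,
          cancer_name = inst$second_entity$normalized_id,
          gm_probability = gene_best[[gkey]]$prob,
          gc_probability = gc_probs[i],
          direction = gene_best[[gkey]]$direction,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (verbose) {
    message(sprintf(
      "extract: %d sentences, %d G-M pairs (%d positive), %d G-C pairs (%d positive)",
      stats["sentences"], stats["gm_pairs"], stats["gm_positive"],
      stats["gc_pairs"], stats["gc_positive"]))
  }
  if (!length(rows)) {
    return(data.frame(document_id = character(0), sentence_index = integer(0),
                      text = character(0), gene_id = character(0),
                      gene_surface = character(0), cancer_name = character(0),
                      gm_probability = numeric(0), gc_probability = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Rank gene-cancer associations over their evidence sentences
#'
#' Groups evidence by (gene_id, cancer_name).  The ranking score of a
#' pair is the sum of the G-C positive probabilities over its evidence
#' sentences; the average maximum probability is that sum divided by
#' the number of sentences.  Associations are ordered by ranking score
#' descending (ties by gene_id then cancer_name); evidence within an
#' association is ordered by probability descending.
#'
#' @param evidence data.frame from \code{\link{extract_evidence}}.
#' @return data.frame with one row per association: \code{gene_id},
#'   \code{cancer_name}, \code{ranking_score}, \code{n_sentences},
#'   \code{average_max_probability}, \code{n_hyper}, \code{n_hypo},
#'   \code{n_unspecified}, plus an \code{evidence} list-column of the
#'   per-association evidence rows.
#' @export
rank_associations <- function(evidence) {
  if (!nrow(evidence)) {
    return(data.frame(gene_id = character(0), cancer_name = character(0),
                      ranking_score = numeric(0), n_sentences = integer(0),
                      average_max_probability = numeric(0),
                      n_hyper = integer(0), n_hypo = integer(0),
                      n_unspecified = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste0(evidence$gene_id, "\t", evidence$cancer_name)
  out <- lapply(unique(key), function(kk) {
    e <- evidence[key == kk, , drop = FALSE]
    e <- e[order(-e$gc_probability), , drop = FALSE]
    score <- sum(e$gc_probability)
    data.frame(gene_id = e$gene_id[1], cancer_name = e$cancer_name[1],
               ranking_score = score, n_sentences = nrow(e),
               average_max_probability = score / nrow(e),
               n_hyper = sum(e$direction == "HYPER"),
               n_hypo = sum(e$direction == "HYPO"),
               n_unspecified = sum(e$direction == "UNSPECIFIED"),
               stringsAsFactors = FALSE)
  })
  ranked <- do.call(rbind, out)
  evid <- lapply(unique(key), function(kk) {
    e <- evidence[key == kk, , drop = FALSE]
    e[order(-e$gc_probability), , drop = FALSE]
  })
  ord <- order(-ranked$ranking_score, ranked$gene_id, ranked$cancer_name)
  ranked <- ranked[ord, , drop = FALSE]
  ranked$evidence <- evid[ord]
  rownames(ranked) <- NULL
  ranked
}

#' Evaluate predicted relation labels against gold
#'
#' A true positive is a predicted-POSITIVE pair whose gold counterpart
#' (same sentence text, same normalized entity pair, same relation
#' kind) is POSITIVE.  Precision and recall follow TP/(TP+FP) and
#' TP/(TP+FN); an empty denominator is reported as 0 with
#' \code{degenerate = TRUE}.
#'
#' @param gold,predicted lists of labeled
#'   \code{\link{relation_instance}}s over the same sentence/pair
#'   universe.
#' @return a \code{match_result}.
#' @export
evaluate_relations <- function(gold, predicted) {
  key <- function(i) paste0(i$relation_kind, "\r", i$sentence$text, "\r",
                            i$first_entity$normalized_id, "\r",
                            i$second_entity$start, "\r",
                            i$second_entity$normalized_id)
  gk <- vapply(gold, key, character(1))
  gl <- vapply(gold, function(i) i$label, character(1))
  pk <- vapply(predicted, key, character(1))
  pl <- vapply(predicted, function(i) i$label, character(1))
  gold_pos <- gk[gl == "POSITIVE"]
  pred_pos <- pk[pl == "POSITIVE"]
  tp <- length(intersect(pred_pos, gold_pos))
  fp <- length(setdiff(pred_pos, gold_pos))
  fn <- length(setdiff(gold_pos, pred_pos))
  match_result(tp, fp, fn, "EXACT")
}
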