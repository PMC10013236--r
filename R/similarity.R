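#' Similarity-labeling configuration
#'
#' Controls the conversion of triple-similarity scores into binary
#' importance labels. A body triple scoring at least `hi` against some
#' abstract triple of the same document is labeled `important`; one
#' scoring at most `lo` against every abstract triple is
#' `not_important`; scores inside the open gap `(lo, hi)` are
#' `discarded_gap` and excluded from training, so that the two classes
#' are well separated. Defaults are the previously optimized thresholds
#' 2.5 and 1.5.
#'
#' With `clamp_negative_cosines = TRUE` (the default) each of the three
#' cosines entering the score is floored at 0, which makes the stated
#' score interval `[0, 3]` hold exactly even for embeddings with
#' negative cosines; raw cosines can be requested instead.
#'
#' @param hi importance threshold (score `>= hi` is important).
#' @param lo non-importance threshold (score `<= lo` is not important).
#' @param clamp_negative_cosines floor each cosine at 0.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(hi = 2.5, lo = 1.5,
                              clamp_negative_cosines = TRUE) {
  stopifnot(is.numeric(hi), is.numeric(lo), lo < hi)
  if (clamp_negative_cosines) stopifnot(lo >= 0, hi <= 3)
  structure(list(hi = hi, lo = lo,
                 clamp_negative_cosines = isTRUE(clamp_negative_cosines)),
            class = "similarity_config")
}

clamp0 <- function(x, on) if (on) max(0, x) else x

#' Three-way cosine-sum similarity between two triples
#'
#' Compares two SPO triples componentwise: subject concept against
#' subject concept and object against object with concept embeddings,
#' predicate against predicate with predicate embeddings. Each cosine
#' has maximum 1; their sum scores the pair in `[0, 3]` (with negative
#' cosines clamped at 0, see [similarity_config()]). The measure is
#' symmetric, and a triple compared with itself scores exactly 3.
#'
#' @param t1,t2 triples: lists or one-row data frames with
#'   `subject_cui`, `predicate`, `object_cui`.
#' @param concepts concept [embedding_store()].
#' @param predicates predicate [embedding_store()].
#' @param config a [similarity_config()].
#' @return Scalar similarity score.
#' @export
triple_similarity <- function(t1, t2, concepts, predicates,
                              config = similarity_config()) {
  cl <- config$clamp_negative_cosines
  s <- clamp0(cosine(concept_vector(concepts, t1$subject_cui),
                     concept_vector(concepts, t2$subject_cui)), cl)
  p <- clamp0(cosine(predicate_vector(predicates, t1$predicate),
                     predicate_vector(predicates, t2$predicate)), cl)
  o <- clamp0(cosine(concept_vector(concepts, t1$object_cui),
                     concept_vector(concepts, t2$object_cui)), cl)
  s + p + o
}

#' Maximum similarity of a body triple against a document's abstract
#'
#' The importance score of a body triple is its maximum
#' [triple_similarity()] over all SPO triples in the same document's
#' abstract. The abstract triple attaining the maximum is attached as
#' attribute `"argmax"` for explainability.
#'
#' @param body a triple (list or one-row data frame).
#' @param abstract_triples data frame of the document's distinct
#'   abstract triples; must be non-empty.
#' @inheritParams triple_similarity
#' @return Scalar maximum score with attribute `argmax` (row index into
#'   `abstract_triples`).
#' @export
max_abstract_similarity <- function(body, abstract_triples, concepts,
                                    predicates,
                                    config = similarity_config()) {
  if (NROW(abstract_triples) == 0L)
    stop_lbd("document has no abstract triples", "lbd_no_abstract")
  scores <- vapply(seq_len(nrow(abstract_triples)), function(i)
    triple_similarity(body, abstract_triples[i, ], concepts, predicates,
                      config), 0)
  best <- which.max(scores)
  structure(scores[best], argmax = best)
}

#' Build the similarity-labeled importance training set
#'
#' Scores every body predication of every document that has at least
#' one abstract triple against that document's abstract, and labels it
#' by the thresholds in `config` (`important` / `not_important` /
#' `discarded_gap`). Documents without abstract triples are skipped and
#' counted, as are predications whose embeddings cannot be resolved; gap
#' instances are retained in the result (for inspection) but are meant
#' to be excluded from training, which [balance_by_undersampling()] and
#' the trainers do.
#'
#' @param corpus an [corpus()] object containing body predications.
#' @inheritParams triple_similarity
#' @return A data frame of class `labeled_triples`: the body
#'   predications plus `score` and `label` columns, with attributes
#'   `n_docs_skipped` (no abstract triples) and `n_missing_embedding`
#'   (unresolvable predications).
#' @export
build_training_set <- function(corpus, concepts, predicates,
                               config = similarity_config()) {
  corpus <- as_corpus(corpus)
  body <- corpus[corpus$section == "body", , drop = FALSE]
  abst <- corpus[corpus$section == "abstract", , drop = FALSE]
  abs_by_doc <- split(seq_len(nrow(abst)), abst$doc_id)
  out <- body
  out$score <- NA_real_
  out$label <- NA_character_
  skipped_docs <- setdiff(unique(body$doc_id), names(abs_by_doc))
  missing_emb <- 0L
  keep <- logical(nrow(body))
  for (i in seq_len(nrow(body))) {
    doc <- body$doc_id[i]
    idx <- abs_by_doc[[doc]]
    if (is.null(idx)) next
    atr <- distinct_triples(abst[idx, , drop = FALSE])
    sc <- tryCatch(
      max_abstract_similarity(body[i, ], atr, concepts, predicates, config),
      lbd_missing_embedding = function(e) NA_real_)
    if (is.na(sc)) {
      missing_emb <- missing_emb + 1L
      next
    }
    out$score[i] <- as.numeric(sc)
    out$label[i] <- score_label(sc, config)
    keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("labeled_triples", "data.frame"),
            n_docs_skipped = length(skipped_docs),
            n_missing_embedding = missing_emb)
}

score_label <- function(score, config) {
  ifelse(score >= config$hi, "important",
         ifelse(score <= config$lo, "not_important", "discarded_gap"))
}

#' Balance a labeled set by random undersampling
#'
#' Randomly undersamples the majority class so the `important` and
#' `not_important` classes have equal size; the minority class is kept
#' untouched and gap instances are dropped. Sampling is reproducible for
#' a fixed seed.
#'
#' @param labeled a `labeled_triples` data frame from
#'   [build_training_set()].
#' @param seed integer RNG seed.
#' @return A balanced `labeled_triples` data frame.
#' @export
balance_by_undersampling <- function(labeled, seed) {
  lab <- labeled[labeled$label %in% c("important", "not_important"), ,
                 drop = FALSE]
  n_imp <- sum(lab$label == "important")
  n_not <- sum(lab$label == "not_important")
  if (n_imp == 0L || n_not == 0L)
    stop_lbd("both importance classes must be non-empty for undersampling",
             "lbd_single_class")
  n <- min(n_imp, n_not)
  pick <- function(which_lab) {
    idx <- which(lab$label == which_lab)
    if (length(idx) == n) idx else with_local_seed(seed, sort(sample(idx, n)))
  }
  out <- lab[sort(c(pick("important"), pick("not_important"))), , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(labeled)
  structure(out, class = c("labeled_triples", "data.frame"),
            n_docs_skipped = attrs$n_docs_skipped,
            n_missing_embedding = attrs$n_missing_embedding)
}

#' Write a labeled set as TSV
#'
#' Predication columns plus `score` (6 decimal places, fixed format so
#' reruns are byte-identical) and `label`.
#'
#' @param labeled a `labeled_triples` data frame.
#' @param path output path.
#' @export
write_labeled_triples <- function(labeled, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  field <- function(x) { x <- as.character(x); x[is.na(x)] <- "-"; x }
  header <- paste0("#", paste(c(pred_columns, "score", "label"),
                              collapse = "\t"))
  body <- if (nrow(labeled)) {
    paste(field(labeled$doc_id), format(labeled$date, "%Y-%m-%d"),
          field(labeled$section), field(labeled$sentence_index),
          field(labeled$sentence_text), field(labeled$subject_cui),
          field(labeled$predicate), field(labeled$object_cui),
          fmt_num(labeled$score), field(labeled$label), sep = "\t")
  } else character()
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
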