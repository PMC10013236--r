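#' Triple language-model configuration
#'
#' Settings for the masked-element language model over SPO triples.
#' Each triple is treated as a three-word sentence over a word-level
#' vocabulary (no subword splitting, since concept identifiers such as
#' `C0012984` have no meaningful subwords). Training hides exactly one
#' of the three positions, chosen uniformly at random per example per
#' epoch, and optimizes prediction of the hidden element from the other
#' two. The two tuned capacity knobs are the vocabulary size and the
#' number of hidden layers.
#'
#' @param vocab_size maximum number of content tokens kept in the
#'   vocabulary (special tokens come on top); overflow tokens map to the
#'   unknown token.
#' @param hidden_layers number of ReLU encoder layers.
#' @param embedding_dim token-embedding dimension; the encoder width
#'   and the triple-embedding dimension are `3 * embedding_dim`.
#' @param epochs training epochs (full batch).
#' @param learning_rate Adam step size.
#' @return A `triple_lm_config` list.
#' @export
triple_lm_config <- function(vocab_size = 200L, hidden_layers = 2L,
                             embedding_dim = 16L, epochs = 150L,
                             learning_rate = 0.02) {
  stopifnot(vocab_size >= 1L, hidden_layers >= 0L, embedding_dim >= 2L)
  structure(list(vocab_size = as.integer(vocab_size),
                 hidden_layers = as.integer(hidden_layers),
                 embedding_dim = as.integer(embedding_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate),
            class = "triple_lm_config")
}

lm_special_tokens <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Word-level triple tokenizer
#'
#' Splits a triple sentence on whitespace into its three content
#' tokens; no subword units are ever produced.
#'
#' @param x character vector of space-separated triple sentences.
#' @return List of token vectors.
#' @export
tokenize_triples <- function(x) strsplit(trimws(x), "\\s+")

# Vocabulary: special tokens first, then content tokens in
# frequency-descending, ties lexicographic, truncated at vocab_size.
build_lm_vocab <- function(tokens, vocab_size) {
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  content <- names(tab)[ord]
  if (length(content) > vocab_size) {
    warning(sprintf(
      "%d distinct tokens exceed vocab_size %d; overflow tokens map to [UNK]",
      length(content), vocab_size))
    content <- content[seq_len(vocab_size)]
  }
  c(lm_special_tokens, content)
}

encode_ids <- function(tokens, vocab) {
  id <- match(tokens, vocab)
  id[is.na(id)] <- match("[UNK]", vocab)
  id
}

triple_id_matrix <- function(triples, vocab) {
  cbind(encode_ids(triples$subject_cui, vocab),
        encode_ids(triples$predicate, vocab),
        encode_ids(triples$object_cui, vocab))
}

# Forward pass of the encoder: token + position embeddings,
# concatenated across the three slots, then hidden_layers ReLU layers
# of constant width 3*embedding_dim.
lm_encode <- function(params, ids) {
  d <- ncol(params$E)
  X <- cbind(params$E[ids[, 1], , drop = FALSE] +
               matrix(params$P[1, ], nrow(ids), d, byrow = TRUE),
             params$E[ids[, 2], , drop = FALSE] +
               matrix(params$P[2, ], nrow(ids), d, byrow = TRUE),
             params$E[ids[, 3], , drop = FALSE] +
               matrix(params$P[3, ], nrow(ids), d, byrow = TRUE))
  acts <- list(X)
  a <- X
  for (l in seq_along(params$W)) {
    a <- relu(sweep(a %*% params$W[[l]], 2, params$b[[l]], "+"))
    acts[[l + 1L]] <- a
  }
  acts
}

#' Train the masked-element triple language model
#'
#' Fits a small encoder over SPO triples by masked-element modeling:
#' per epoch, each training triple has one of its three positions
#' replaced by the mask token (uniformly at random) and the model is
#' trained by softmax cross-entropy to recover the hidden token from
#' the other two. The trained encoder yields a fixed-dimension
#' embedding per triple (see [triple_embeddings()]) for downstream
#' classification.
#'
#' @param triples data frame of distinct triples (`subject_cui`,
#'   `predicate`, `object_cui`).
#' @param config a [triple_lm_config()].
#' @param seed integer seed (initialization and masking).
#' @return An object of class `triple_lm`.
#' @export
train_triple_lm <- function(triples, config = triple_lm_config(), seed = 1L) {
  triples <- distinct_triples(triples)
  if (!nrow(triples)) stop("at least one triple is required")
  tokens <- c(triples$subject_cui, triples$predicate, triples$object_cui)
  vocab <- build_lm_vocab(tokens, config$vocab_size)
  ids <- triple_id_matrix(triples, vocab)
  V <- length(vocab)
  d <- config$embedding_dim
  width <- 3L * d
  H <- config$hidden_layers
  mask_id <- match("[MASK]", vocab)
  n <- nrow(ids)
  with_local_seed(seed, {
    params <- list(E = he_init(V, d) * 0.1, P = he_init(3L, d) * 0.1,
                   W = lapply(seq_len(H), function(l) he_init(width, width)),
                   b = lapply(seq_len(H), function(l) rep(0, width)),
                   U = he_init(width, V), u0 = rep(0, V))
    flat <- c(list(params$E, params$P), params$W, params$b,
              list(params$U, params$u0))
    st <- adam_new(flat)
    loss_traj <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      pos <- sample.int(3L, n, replace = TRUE)
      masked <- ids
      masked[cbind(seq_len(n), pos)] <- mask_id
      target <- ids[cbind(seq_len(n), pos)]
      acts <- lm_encode(params, masked)
      hlast <- acts[[length(acts)]]
      logits <- sweep(hlast %*% params$U, 2, params$u0, "+")
      logits <- logits - apply(logits, 1, max)
      expl <- exp(logits)
      probs <- expl / rowSums(expl)
      loss_traj[ep] <- -mean(log(pmax(probs[cbind(seq_len(n), target)],
                                      1e-12)))
      dlog <- probs
      dlog[cbind(seq_len(n), target)] <- dlog[cbind(seq_len(n), target)] - 1
      dlog <- dlog / n
      gU <- crossprod(hlast, dlog)
      gu0 <- colSums(dlog)
      delta <- dlog %*% t(params$U)
      gW <- vector("list", H)
      gb <- vector("list", H)
      for (l in rev(seq_len(H))) {
        delta <- delta * (acts[[l + 1L]] > 0)
        gW[[l]] <- crossprod(acts[[l]], delta)
        gb[[l]] <- colSums(delta)
        delta <- delta %*% t(params$W[[l]])
      }
      # delta is now the gradient w.r.t. the concatenated input X
      gE <- matrix(0, V, d)
      gP <- matrix(0, 3L, d)
      for (k in 1:3) {
        blk <- delta[, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
        gP[k, ] <- colSums(blk)
        agg <- rowsum(blk, group = masked[, k])
        gE[as.integer(rownames(agg)), ] <-
          gE[as.integer(rownames(agg)), , drop = FALSE] + agg
      }
      flat <- c(list(params$E, params$P), params$W, params$b,
                list(params$U, params$u0))
      gflat <- c(list(gE, gP), gW, gb, list(gU, gu0))
      upd <- adam_step(flat, gflat, st, lr = config$learning_rate)
      st <- upd$state
      params$E <- upd$params[[1L]]
      params$P <- upd$params[[2L]]
      if (H > 0L) {
        params$W <- upd$params[2L + seq_len(H)]
        params$b <- upd$params[2L + H + seq_len(H)]
      }
      params$U <- upd$params[[2L + 2L * H + 1L]]
      params$u0 <- drop(upd$params[[2L + 2L * H + 2L]])
    }
    structure(list(params = params, vocab = vocab, config = config,
                   loss = loss_traj, n_triples = n),
              class = "triple_lm")
  })
}

#' @export
print.triple_lm <- function(x, ...) {
  cat(sprintf(
    "<triple_lm> vocab %d (+%d special), %d hidden layer(s), dim %d, final loss %.4f\n",
    length(x$vocab) - length(lm_special_tokens), length(lm_special_tokens),
    x$config$hidden_layers, x$config$embedding_dim,
    x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict a masked triple element
#'
#' Masks the requested position of a triple and returns the model's
#' distribution over the vocabulary for it.
#'
#' @param lm a [train_triple_lm()] model.
#' @param triple list/one-row data frame with `subject_cui`,
#'   `predicate`, `object_cui`.
#' @param position which element to hide: 1 subject, 2 predicate,
#'   3 object.
#' @return List with `token` (top-1 prediction) and `probabilities`
#'   (named vector over the vocabulary).
#' @export
predict_masked <- function(lm, triple, position) {
  stopifnot(position %in% 1:3)
  ids <- triple_id_matrix(as.data.frame(triple), lm$vocab)
  ids[1, position] <- match("[MASK]", lm$vocab)
  acts <- lm_encode(lm$params, ids)
  logits <- drop(acts[[length(acts)]] %*% lm$params$U) + lm$params$u0
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  names(p) <- lm$vocab
  list(token = lm$vocab[which.max(p)], probabilities = p)
}

#' Triple embeddings from the language model
#'
#' Encodes unmasked triples with the trained encoder; the final hidden
#' activation is the triple's fixed-dimension embedding.
#'
#' @param lm a [train_triple_lm()] model.
#' @param triples data frame of triples.
#' @return Numeric matrix, one row per triple.
#' @export
triple_embeddings <- function(lm, triples) {
  ids <- triple_id_matrix(as.data.frame(triples), lm$vocab)
  acts <- lm_encode(lm$params, ids)
  acts[[length(acts)]]
}

#' Fine-tune a binary importance head on the language model
#'
#' Trains a sigmoid classification head over the frozen language
#' model's triple embeddings with binary cross-entropy, using the
#' similarity-labeled training set (gap instances excluded).
#'
#' @param lm a [train_triple_lm()] model.
#' @param labeled a `labeled_triples` data frame with both classes.
#' @param seed integer seed for head initialization.
#' @param epochs,learning_rate head training settings.
#' @return An object of class `triple_lm_classifier`.
#' @export
finetune_classifier <- function(lm, labeled, seed = 1L, epochs = 300L,
                                learning_rate = 0.05) {
  lab <- labeled[labeled$label %in% c("important", "not_important"), ,
                 drop = FALSE]
  y <- as.integer(lab$label == "important")
  if (length(unique(y)) < 2L)
    stop_lbd("fine-tuning requires both importance classes",
             "lbd_single_class")
  X <- triple_embeddings(lm, lab)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  net <- mlp_train_binary(Xs, y, hidden = integer(), epochs = epochs,
                          lr = learning_rate, seed = seed)
  structure(list(lm = lm, net = net, center = center, scale = scale,
                 n_train = nrow(lab)),
            class = "triple_lm_classifier")
}

#' Predict triple importance with the fine-tuned language model
#'
#' @param classifier a [finetune_classifier()] object.
#' @param triples data frame of triples.
#' @return Data frame with `probability` in (0, 1) and `label`
#'   (`important` iff probability > 0.5).
#' @export
predict_triple_importance <- function(classifier, triples) {
  X <- triple_embeddings(classifier$lm, as.data.frame(triples))
  Xs <- sweep(sweep(X, 2, classifier$center, "-"), 2, classifier$scale, "/")
  p <- as.numeric(mlp_predict_binary(classifier$net, Xs))
  data.frame(probability = p,
             label = ifelse(p > 0.5, "important", "not_important"),
             stringsAsFactors = FALSE)
}
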