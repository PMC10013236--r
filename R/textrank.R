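#' TextRank sentence scores
#'
#' Ranks the sentences of a document by a damped random walk over the
#' sentence-similarity graph, the classic TextRank construction: an
#' undirected graph with one vertex per sentence whose edge weights are
#' the shared-token counts normalized by the sum of the log sentence
#' lengths, iterated to its stationary distribution with damping 0.85.
#' The sentence score is used as one feature of the feature-based
#' importance classifier (the score of the sentence a triple was
#' extracted from).
#'
#' Scores are sum-normalized to 1; a single sentence scores 1 and
#' identical sentences score equally. For sentence pairs where both
#' lengths are 1 the log-length normalizer vanishes, and the raw overlap
#' count is used instead.
#'
#' @param sentences list of character vectors, one vector of tokens per
#'   sentence, in document order.
#' @param damping damping factor of the random walk.
#' @param tol convergence tolerance on the L1 change per iteration.
#' @param max_iter iteration cap.
#' @return Named numeric vector of scores; names are 0-based sentence
#'   indices (matching `sentence_index` in predication files).
#' @export
compute_textrank <- function(sentences, damping = 0.85, tol = 1e-6,
                             max_iter = 100L) {
  n <- length(sentences)
  if (n == 0L) stop("compute_textrank requires at least one sentence")
  idx_names <- as.character(seq_len(n) - 1L)
  if (n == 1L) return(stats::setNames(1, idx_names))
  W <- matrix(0, n, n)
  lens <- lengths(sentences)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ov <- length(intersect(unique(sentences[[i]]), unique(sentences[[j]])))
      if (ov == 0) next
      denom <- log(lens[i]) + log(lens[j])
      if (denom <= 0) denom <- 1
      W[i, j] <- W[j, i] <- ov / denom
    }
  }
  r <- textrank_power_iteration(W, damping, tol, max_iter)
  stats::setNames(r / sum(r), idx_names)
}

# Damped power iteration on a weighted undirected graph; columns of the
# transition matrix are weight-normalized, dangling vertices jump
# uniformly.
textrank_power_iteration <- function(W, damping, tol, max_iter) {
  n <- nrow(W)
  deg <- colSums(W)
  dangling <- deg == 0
  P <- W
  P[, !dangling] <- sweep(W[, !dangling, drop = FALSE], 2,
                          deg[!dangling], "/")
  P[, dangling] <- 1 / n
  r <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    r_new <- (1 - damping) / n + damping * as.vector(P %*% r)
    if (sum(abs(r_new - r)) < tol) return(r_new)
    r <- r_new
  }
  r
}
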