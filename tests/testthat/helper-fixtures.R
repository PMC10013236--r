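# Shared fixtures, built in code.

# Stores over 4-d integer-coordinate vectors whose pairwise cosines are
# exact in floating point: dot products and squared norms are small
# integers, so e.g. cos = 2/(2*2) = 0.5 exactly.
exact_cosine_stores <- function() {
  e1 <- c(1, 1, 1, 1)      # |e1| = 2
  half <- c(1, 1, 1, -1)   # cos(e1, half) = 2/4 = 0.5 exactly
  orth <- c(1, -1, 1, -1)  # cos(e1, orth) = 0
  cm <- rbind(CA = e1, CB = e1, CH = half, CO = orth)
  pm <- rbind(SAME = e1, HALF = half, ORTH = orth)
  list(concepts = embedding_store(cm, "concept"),
       predicates = embedding_store(pm, "predicate"))
}

random_stores <- function(keys, preds, dim = 10, seed = 1) {
  set.seed(seed)
  cm <- matrix(rnorm(length(keys) * dim), length(keys),
               dimnames = list(keys))
  pm <- matrix(rnorm(length(preds) * dim), length(preds),
               dimnames = list(preds))
  list(concepts = embedding_store(cm, "concept"),
       predicates = embedding_store(pm, "predicate"))
}

random_corpus <- function(n = 100, seed = 1) {
  set.seed(seed)
  corpus(doc_id = sprintf("d%03d", sample(20, n, replace = TRUE)),
         date = as.Date("2020-01-01") + sample(0:730, n, replace = TRUE),
         section = sample(c("abstract", "body"), n, replace = TRUE),
         sentence_index = ifelse(runif(n) < 0.8,
                                 sample(0:9, n, replace = TRUE), NA),
         sentence_text = ifelse(runif(n) < 0.8,
                                replicate(n, paste(sample(letters, 4),
                                                   collapse = " ")), NA),
         subject_cui = sprintf("C%07d", sample(50, n, replace = TRUE)),
         predicate = sample(c("TREATS", "CAUSES", "ISA", "PROCESS_OF"),
                            n, replace = TRUE),
         object_cui = sprintf("C%07d", sample(50, n, replace = TRUE)))
}

random_triples <- function(n = 200, n_cuis = 30, seed = 1) {
  set.seed(seed)
  data.frame(subject_cui = sprintf("V%02d", sample(n_cuis, n, replace = TRUE)),
             predicate = "REL",
             object_cui = sprintf("V%02d", sample(n_cuis, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

# Dense middle-vertex enumeration of two-step walk counts -- the
# brute-force counterpart of sparse adjacency squaring.
walk2_bruteforce <- function(A) {
  V <- nrow(A)
  S <- matrix(0, V, V)
  for (k in seq_len(V)) S <- S + outer(A[, k], A[k, ])
  S
}

dense_adjacency <- function(graph) {
  as.matrix(graph$adjacency) * 1
}
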