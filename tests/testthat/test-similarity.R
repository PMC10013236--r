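tri <- function(s, p, o) list(subject_cui = s, predicate = p, object_cui = o)

test_that("a triple compared with itself scores exactly 3", {
  st <- random_stores(c("C1", "C2"), c("TREATS"), seed = 2)
  t1 <- tri("C1", "TREATS", "C2")
  expect_identical(triple_similarity(t1, t1, st$concepts, st$predicates), 3)
})

test_that("identical concepts with orthogonal predicates score exactly 2", {
  st <- exact_cosine_stores()
  a <- tri("CA", "SAME", "CB")
  b <- tri("CA", "ORTH", "CB")
  expect_identical(triple_similarity(a, b, st$concepts, st$predicates), 2)
})

test_that("the score is the sum of three independently computed cosines", {
  st <- random_stores(sprintf("C%d", 1:4), c("TREATS", "CAUSES"),
                      dim = 10, seed = 7)
  t1 <- tri("C1", "TREATS", "C2")
  t2 <- tri("C3", "CAUSES", "C4")
  # per-component oracle, computed directly from the raw matrices
  cc <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cm <- st$concepts$vectors; pm <- st$predicates$vectors
  expected <- max(0, cc(cm["C1", ], cm["C3", ])) +
    max(0, cc(pm["TREATS", ], pm["CAUSES", ])) +
    max(0, cc(cm["C2", ], cm["C4", ]))
  expect_equal(triple_similarity(t1, t2, st$concepts, st$predicates), expected)
  expect_equal(triple_similarity(t2, t1, st$concepts, st$predicates),
               triple_similarity(t1, t2, st$concepts, st$predicates))
})

test_that("clamping keeps scores in [0, 3]; raw mode can go negative", {
  cm <- rbind(P = c(1, 0), N = c(-1, 0))
  pm <- rbind(R = c(1, 1))
  co <- embedding_store(cm, "concept"); pr <- embedding_store(pm, "predicate")
  a <- tri("P", "R", "P"); b <- tri("N", "R", "N")
  clamped <- triple_similarity(a, b, co, pr)
  expect_identical(clamped, 1)   # 0 + 1 + 0
  raw <- triple_similarity(a, b, co, pr,
                           similarity_config(clamp_negative_cosines = FALSE))
  expect_identical(raw, -1)      # -1 + 1 - 1
})

test_that("symmetry and the [0,3] interval hold over random stores", {
  st <- random_stores(sprintf("C%d", 1:8), sprintf("R%d", 1:3),
                      dim = 6, seed = 9)
  set.seed(5)
  for (i in 1:30) {
    t1 <- tri(sample(sprintf("C%d", 1:8), 1), sample(sprintf("R%d", 1:3), 1),
              sample(sprintf("C%d", 1:8), 1))
    t2 <- tri(sample(sprintf("C%d", 1:8), 1), sample(sprintf("R%d", 1:3), 1),
              sample(sprintf("C%d", 1:8), 1))
    s <- triple_similarity(t1, t2, st$concepts, st$predicates)
    expect_gte(s, 0); expect_lte(s, 3)
    expect_equal(s, triple_similarity(t2, t1, st$concepts, st$predicates))
  }
})

test_that("max_abstract_similarity is the exhaustive maximum over pairs", {
  st <- random_stores(sprintf("C%d", 1:12), sprintf("R%d", 1:4),
                      dim = 8, seed = 13)
  set.seed(21)
  abst <- data.frame(subject_cui = sample(sprintf("C%d", 1:12), 20, TRUE),
                     predicate = sample(sprintf("R%d", 1:4), 20, TRUE),
                     object_cui = sample(sprintf("C%d", 1:12), 20, TRUE),
                     stringsAsFactors = FALSE)
  body <- tri("C5", "R2", "C9")
  brute <- max(vapply(seq_len(nrow(abst)), function(i)
    triple_similarity(body, abst[i, ], st$concepts, st$predicates), 0))
  got <- max_abstract_similarity(body, abst, st$concepts, st$predicates)
  expect_equal(as.numeric(got), brute)
  expect_true(!is.null(attr(got, "argmax")))
  # a body triple also present verbatim in the abstract scores 3
  expect_equal(as.numeric(max_abstract_similarity(
    tri(abst$subject_cui[1], abst$predicate[1], abst$object_cui[1]),
    abst, st$concepts, st$predicates)), 3)
  expect_error(max_abstract_similarity(body, abst[0, ], st$concepts,
                                       st$predicates),
               class = "lbd_no_abstract")
})

# Fixture engineered so body triples score exactly 2.5, 1.5, 2.0:
# pairwise cosines of the store vectors are exact (0, 0.5, 1).
threshold_fixture <- function() {
  st <- exact_cosine_stores()
  co <- corpus(
    doc_id = "d1", date = "2021-01-05",
    section = c("abstract", "body", "body", "body"),
    subject_cui = c("CA", "CA", "CA", "CA"),
    predicate = c("SAME", "HALF", "ORTH", "ORTH"),
    object_cui = c("CB", "CB", "CH", "CB"))
  list(stores = st, corpus = co)
}

test_that("threshold semantics: 2.5 is important, 1.5 not important, 2.0 gap", {
  fx <- threshold_fixture()
  lab <- build_training_set(fx$corpus, fx$stores$concepts,
                            fx$stores$predicates)
  expect_equal(nrow(lab), 3L)
  # cos(subj)=1, cos(SAME,HALF)=0.5, cos(obj)=1 -> exactly 2.5 -> important
  expect_identical(lab$score[1], 2.5)
  expect_equal(lab$label[1], "important")
  # 1 + 0 + cos(CB,CH)=0.5 -> exactly 1.5 -> not important
  expect_identical(lab$score[2], 1.5)
  expect_equal(lab$label[2], "not_important")
  # 1 + 0 + 1 -> exactly 2.0 -> inside the gap, discarded
  expect_identical(lab$score[3], 2)
  expect_equal(lab$label[3], "discarded_gap")
})

test_that("documents without abstract triples are skipped and counted", {
  fx <- threshold_fixture()
  extra <- corpus(doc_id = "d2", date = "2021-01-06", section = "body",
                  subject_cui = "CA", predicate = "SAME", object_cui = "CB")
  co <- as_corpus(rbind(as.data.frame(fx$corpus), as.data.frame(extra)))
  lab <- build_training_set(co, fx$stores$concepts, fx$stores$predicates)
  expect_equal(attr(lab, "n_docs_skipped"), 1L)
  expect_true(all(lab$doc_id == "d1"))
})

test_that("predications with unresolvable embeddings are skipped and counted", {
  fx <- threshold_fixture()
  extra <- corpus(doc_id = "d1", date = "2021-01-05", section = "body",
                  subject_cui = "CUNKNOWN", predicate = "SAME",
                  object_cui = "CB")
  co <- as_corpus(rbind(as.data.frame(fx$corpus), as.data.frame(extra)))
  lab <- build_training_set(co, fx$stores$concepts, fx$stores$predicates)
  expect_equal(attr(lab, "n_missing_embedding"), 1L)
  expect_equal(nrow(lab), 3L)
})

test_that("undersampling equalizes classes, keeps the minority, and is seeded", {
  lab <- structure(
    data.frame(doc_id = "d", date = as.Date("2021-01-01"), section = "body",
               sentence_index = NA_integer_, sentence_text = NA_character_,
               subject_cui = sprintf("C%d", 1:50), predicate = "R",
               object_cui = "CX",
               score = c(rep(3, 10), rep(0, 40)),
               label = c(rep("important", 10), rep("not_important", 40)),
               stringsAsFactors = FALSE),
    class = c("labeled_triples", "data.frame"))
  bal <- balance_by_undersampling(lab, seed = 4)
  expect_equal(sum(bal$label == "important"), 10L)
  expect_equal(sum(bal$label == "not_important"), 10L)
  expect_setequal(bal$subject_cui[bal$label == "important"],
                  sprintf("C%d", 1:10))       # minority untouched
  bal2 <- balance_by_undersampling(lab, seed = 4)
  expect_identical(bal, bal2)                  # same seed, same selection
  bal3 <- balance_by_undersampling(lab, seed = 5)
  expect_false(identical(bal$subject_cui, bal3$subject_cui))
  already <- lab[c(1:10, 11:20), ]
  expect_equal(nrow(balance_by_undersampling(already, 1)), 20L)
  expect_error(balance_by_undersampling(lab[1:10, ], 1),
               class = "lbd_single_class")
})
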