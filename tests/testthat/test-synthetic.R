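test_that("generation is deterministic: byte-identical files for a fixed seed", {
  spec <- synthetic_spec(n_docs = 10, seed = 5)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_predications(gen_corpus(spec), f1)
  write_predications(gen_corpus(spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  e1 <- gen_embeddings(spec); e2 <- gen_embeddings(spec)
  expect_identical(e1$concepts$vectors, e2$concepts$vectors)
  expect_identical(e1$predicates$vectors, e2$predicates$vectors)
  # a different seed changes the corpus
  expect_false(identical(as.data.frame(gen_corpus(spec)),
                         as.data.frame(gen_corpus(synthetic_spec(
                           n_docs = 10, seed = 6)))))
})

test_that("the concept store holds n_concepts unit vectors", {
  spec <- synthetic_spec(n_docs = 4, n_concepts = 10, planted_hidden = 0,
                         background_pool = 2, background_per_doc = 1,
                         embedding_dim = 4, seed = 2)
  emb <- gen_embeddings(spec)
  expect_equal(nrow(emb$concepts$vectors), 10L)
  expect_equal(embedding_dim(emb$concepts), 4L)
  norms <- sqrt(rowSums(emb$concepts$vectors^2))
  expect_equal(unname(norms), rep(1, 10))
})

test_that("novel-role and background concepts are orthogonal by construction", {
  spec <- synthetic_spec(n_docs = 10, seed = 8)
  emb <- gen_embeddings(spec)
  co <- gen_corpus(spec)
  roles <- attr(co, "triple_roles")
  novel <- roles[roles$role == "novel", ][1, ]
  bg <- roles[roles$role == "background", ][1, ]
  s <- triple_similarity(novel, bg, emb$concepts, emb$predicates)
  expect_identical(s, 0)
})

test_that("per-document composition matches the generator settings", {
  spec <- synthetic_spec(n_docs = 1, n_concepts = 12, planted_hidden = 0,
                         novel_per_doc = 1, background_pool = 3,
                         background_per_doc = 2, seed = 3)
  co <- gen_corpus(spec)
  expect_equal(sum(co$section == "abstract"), 1L)
  expect_equal(sum(co$section == "body"), 3L)  # 1 novel + 2 background
})

test_that("planted chains appear pre-cutoff and their A->C pairs post-cutoff", {
  spec <- synthetic_spec(n_docs = 20, planted_hidden = 3, n_concepts = 70,
                         seed = 4)
  co <- gen_corpus(spec)
  pp <- planted_pairs(spec)
  expect_equal(nrow(pp), 3L)
  sl <- timeslice(co, spec$cutoff)
  pre_keys <- paste(sl$pre$subject_cui, sl$pre$object_cui)
  post_keys <- paste(sl$post$subject_cui, sl$post$object_cui)
  for (i in 1:3) {
    expect_true(paste(pp$a[i], pp$b[i]) %in% pre_keys)
    expect_true(paste(pp$b[i], pp$c[i]) %in% pre_keys)
    expect_false(paste(pp$a[i], pp$c[i]) %in% pre_keys)
    expect_true(paste(pp$a[i], pp$c[i]) %in% post_keys)
  }
})

test_that("noise-free labeling has no gap instances and matches planted roles", {
  spec <- synthetic_spec(n_docs = 30, noise_rate = 0, seed = 12)
  emb <- gen_embeddings(spec)
  co <- gen_corpus(spec)
  lab <- build_training_set(co, emb$concepts, emb$predicates)
  expect_equal(sum(lab$label == "discarded_gap"), 0L)
  roles <- attr(co, "triple_roles")
  key <- function(d) paste(d$subject_cui, d$predicate, d$object_cui)
  role <- roles$role[match(key(lab), key(roles))]
  planted_label <- ifelse(role == "background", "not_important", "important")
  expect_equal(lab$label, planted_label)
  expect_true(all(lab$score[lab$label == "important"] == 3))
  expect_true(all(lab$score[lab$label == "not_important"] == 0))
})

test_that("hard mode plants gap scores of 1 + sqrt(2) that are discarded", {
  spec <- synthetic_spec(n_docs = 30, noise_rate = 1, seed = 13)
  emb <- gen_embeddings(spec)
  co <- gen_corpus(spec)
  roles <- attr(co, "triple_roles")
  expect_gt(sum(roles$role == "noise"), 0)
  lab <- build_training_set(co, emb$concepts, emb$predicates)
  gap <- lab[lab$label == "discarded_gap", ]
  expect_gt(nrow(gap), 0)
  expect_equal(unique(round(gap$score, 6)), round(1 + sqrt(2), 6))
})

test_that("hierarchy depths equal BFS distances from the root", {
  spec <- synthetic_spec(n_docs = 6, seed = 14)
  h <- gen_hierarchy(spec)
  root <- attr(h, "root")
  all_nodes <- unique(c(h$parent, h$child))
  d <- cui_depth(h, all_nodes)
  expect_true(all(!is.na(d)))
  g <- igraph::graph_from_data_frame(h[, c("parent", "child")])
  bfs <- as.vector(igraph::distances(g, v = root, to = all_nodes,
                                     mode = "out"))
  expect_equal(as.numeric(d), bfs)
})

test_that("single-concept hierarchy is the root at depth 0", {
  spec <- synthetic_spec(n_docs = 2, n_concepts = 10, planted_hidden = 0,
                         background_pool = 2, seed = 1)
  h <- gen_hierarchy(spec)
  expect_equal(cui_depth(h, attr(h, "root")), 0L)
})

test_that("important-triple LBD emits strictly fewer CHKPs than all-triple LBD", {
  spec <- synthetic_spec(n_docs = 30, seed = 15)
  emb <- gen_embeddings(spec)
  co <- gen_corpus(spec)
  sl <- timeslice(co, spec$cutoff)
  pre_tri <- distinct_triples(sl$pre)
  lab_pre <- build_training_set(sl$pre, emb$concepts, emb$predicates)
  key <- function(d) paste(d$subject_cui, d$predicate, d$object_cui)
  imp <- pre_tri[key(pre_tri) %in% key(lab_pre[lab_pre$label == "important", ]), ]
  ck_all <- extract_chkps(build_graph(pre_tri))
  ck_imp <- extract_chkps(build_graph(imp))
  expect_lt(nrow(ck_imp), nrow(ck_all))
  # the important CHKPs are exactly the planted pairs
  pp <- planted_pairs(spec)
  expect_setequal(paste(ck_imp$source_cui, ck_imp$target_cui),
                  paste(pp$a, pp$c))
})

test_that("an over-committed concept budget is rejected", {
  expect_error(synthetic_spec(n_concepts = 10, planted_hidden = 5,
                              background_pool = 10), "inconsistent spec")
})
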