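mini_corpus <- function(rows) {
  as_corpus(do.call(rbind, lapply(rows, function(r)
    data.frame(doc_id = r[[1]], date = as.Date(r[[2]]), section = r[[3]],
               sentence_index = NA_integer_, sentence_text = NA_character_,
               subject_cui = r[[4]], predicate = r[[5]], object_cui = r[[6]],
               stringsAsFactors = FALSE))))
}

test_that("timeslice partitions and places the boundary day in 'post'", {
  co <- random_corpus(80, seed = 14)
  sl <- timeslice(co, "2020-08-01")
  expect_equal(nrow(sl$pre) + nrow(sl$post), nrow(co))
  expect_true(all(sl$pre$date < as.Date("2020-08-01")))
  expect_true(all(sl$post$date >= as.Date("2020-08-01")))
  all_pre <- timeslice(co, "2030-01-01")
  expect_equal(nrow(all_pre$pre), nrow(co))
  expect_equal(nrow(all_pre$post), 0L)
  boundary <- timeslice(corpus(doc_id = "d", date = "2021-01-01",
                               section = "body", subject_cui = "C1",
                               predicate = "ISA", object_cui = "C2"),
                        "2021-01-01")
  expect_equal(nrow(boundary$post), 1L)
})

test_that("gold-standard variants filter and project as specified", {
  post <- mini_corpus(list(
    list("p1", "2021-02-01", "abstract", "A", "R", "B"),
    list("p1", "2021-02-01", "abstract", "C", "R", "D"),
    list("p1", "2021-02-01", "body", "E", "R", "F")))
  g_all <- build_gold_standard(post, "all_post_triples")
  g_abs <- build_gold_standard(post, "post_abstract_triples")
  expect_equal(nrow(g_all$pairs), 3L)
  expect_equal(nrow(g_abs$pairs), 2L)
  labels <- data.frame(subject_cui = "A", predicate = "R", object_cui = "B",
                       label = "important", stringsAsFactors = FALSE)
  g_imp <- build_gold_standard(post, "post_important_triples", labels)
  expect_equal(g_imp$pairs, data.frame(source_cui = "A", target_cui = "B",
                                       stringsAsFactors = FALSE))
  expect_error(build_gold_standard(post, "post_important_triples"),
               "importance_labels")
  # empty important gold is allowed
  none <- labels[0, ]
  expect_equal(nrow(build_gold_standard(post, "post_important_triples",
                                        none)$pairs), 0L)
})

test_that("gold pairs equal brute-force filter+project on a random corpus", {
  co <- random_corpus(150, seed = 15)
  g <- build_gold_standard(co, "post_abstract_triples")
  brute <- unique(paste(co$subject_cui[co$section == "abstract"],
                        co$object_cui[co$section == "abstract"]))
  expect_setequal(paste(g$pairs$source_cui, g$pairs$target_cui), brute)
})

test_that("precision is the exact intersection fraction", {
  ck <- structure(data.frame(source_cui = sprintf("S%d", 1:5),
                             target_cui = sprintf("T%d", 1:5),
                             linking_count = 1L, stringsAsFactors = FALSE),
                  class = c("chkp_set", "data.frame"))
  gold <- structure(list(variant = "all_post_triples",
                         pairs = data.frame(source_cui = c("S1", "S3", "X"),
                                            target_cui = c("T1", "T3", "Y"),
                                            stringsAsFactors = FALSE)),
                    class = "gold_standard")
  expect_equal(precision(ck, gold), 0.4)
  sub <- gold; sub$pairs <- data.frame(source_cui = sprintf("S%d", 1:5),
                                       target_cui = sprintf("T%d", 1:5))
  expect_equal(precision(ck, sub), 1.0)
  disj <- gold; disj$pairs <- data.frame(source_cui = "X", target_cui = "Y")
  expect_equal(precision(ck, disj), 0.0)
  expect_error(precision(ck[0, ], gold), class = "lbd_empty_chkps")
  # unordered matching counts reversed pairs
  rev <- gold; rev$pairs <- data.frame(source_cui = "T1", target_cui = "S1")
  expect_equal(precision(ck, rev), 0.0)
  expect_equal(precision(ck, rev, unordered = TRUE), 0.2)
})

test_that("evaluate reproduces a hand-enumerated fixture exactly", {
  # pre edges A->B, B->C, D->B; two-step walks: A->B->C and D->B->C,
  # neither a known edge, so CHKPs = {(A,C), (D,C)}
  pre <- data.frame(subject_cui = c("A", "B", "D"), predicate = "R",
                    object_cui = c("B", "C", "B"), stringsAsFactors = FALSE)
  post <- mini_corpus(list(
    list("p1", "2021-03-01", "abstract", "A", "R", "C"),
    list("p1", "2021-03-01", "body", "Q", "R", "Z")))
  rep <- evaluate(pre, post,
                  variants = c("all_post_triples", "post_abstract_triples"))
  expect_equal(rep$total_chkps, 2L)
  expect_setequal(paste(rep$chkps$source_cui, rep$chkps$target_cui),
                  c("A C", "D C"))
  # gold(all) = {(A,C),(Q,Z)}; gold(abstract) = {(A,C)}; hits = {(A,C)}
  expect_equal(unname(rep$precision["all_post_triples"]), 0.5)
  expect_equal(unname(rep$precision["post_abstract_triples"]), 0.5)
  expect_equal(unname(rep$precision_percent["post_abstract_triples"]), 50)
  expect_equal(unname(rep$gold_sizes),
               c(2L, 1L))
  # (D,C) is in no gold standard: the undiscovered export
  expect_equal(paste(rep$undiscovered$source_cui,
                     rep$undiscovered$target_cui), "D C")
})

test_that("evaluate with no variants reports counts only", {
  pre <- data.frame(subject_cui = c("A", "B"), predicate = "R",
                    object_cui = c("B", "C"), stringsAsFactors = FALSE)
  post <- mini_corpus(list(list("p1", "2021-03-01", "abstract", "A", "R", "C")))
  rep <- evaluate(pre, post, variants = character())
  expect_equal(rep$total_chkps, 1L)
  expect_length(rep$precision, 0)
})

test_that("identical pre and post triples give precision 0 by disjointness", {
  co <- mini_corpus(list(
    list("d1", "2020-05-01", "abstract", "A", "R", "B"),
    list("d1", "2020-05-01", "abstract", "B", "R", "C"),
    list("d2", "2021-05-01", "abstract", "A", "R", "B"),
    list("d2", "2021-05-01", "abstract", "B", "R", "C")))
  sl <- timeslice(co, "2021-01-01")
  rep <- evaluate(distinct_triples(sl$pre), sl$post,
                  variants = "post_abstract_triples")
  expect_equal(rep$total_chkps, 1L)
  expect_equal(unname(rep$precision[1]), 0)
})

test_that("precision is monotone over nested gold standards", {
  co <- random_corpus(200, seed = 16)
  sl <- timeslice(co, "2020-10-01")
  # labels restricted to abstract triples so the golds nest:
  # all >= abstract >= important
  abs_tri <- distinct_triples(sl$post[sl$post$section == "abstract", ])
  set.seed(3)
  lab <- abs_tri[sample(nrow(abs_tri), ceiling(nrow(abs_tri) / 3)), ]
  lab$label <- "important"
  rep <- evaluate(distinct_triples(sl$pre), sl$post,
                  importance_labels = lab)
  p <- rep$precision
  expect_gte(p[["all_post_triples"]], p[["post_abstract_triples"]])
  expect_gte(p[["post_abstract_triples"]], p[["post_important_triples"]])
})

test_that("the eval report TSV is stable across reruns", {
  pre <- data.frame(subject_cui = c("A", "B"), predicate = "R",
                    object_cui = c("B", "C"), stringsAsFactors = FALSE)
  post <- mini_corpus(list(list("p1", "2021-03-01", "abstract", "A", "R", "C")))
  rep <- evaluate(pre, post, variants = "post_abstract_triples")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_eval_report(rep, f1)
  write_eval_report(evaluate(pre, post, variants = "post_abstract_triples"), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[2], "1\t1\t1.000000\t100.0000")
})
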