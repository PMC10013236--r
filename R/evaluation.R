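#' Timeslice a corpus at a cutoff date
#'
#' Splits a corpus into the "pre" part (dates strictly before the
#' cutoff, used to generate CHKPs) and the "post" part (dates on or
#' after the cutoff, used to build gold standards). The two parts
#' partition the corpus.
#'
#' @param corpus an [corpus()] object.
#' @param cutoff cutoff date `D`.
#' @return List with elements `pre` and `post`.
#' @export
timeslice <- function(corpus, cutoff) {
  list(pre = filter_corpus(corpus, before = cutoff),
       post = filter_corpus(corpus, on_or_after = cutoff))
}

gold_variants <- c("all_post_triples", "post_abstract_triples",
                   "post_important_triples")

#' Build a timeslicing gold standard
#'
#' A gold standard is the set of ordered (subject, object) concept
#' pairs appearing in post-cutoff predications, under one of three
#' variants of decreasing background-knowledge contamination:
#' `all_post_triples` (every post-cutoff predication),
#' `post_abstract_triples` (abstract predications only), and
#' `post_important_triples` (only triples carrying an `important`
#' label, which must be supplied).
#'
#' @param post the post-cutoff corpus from [timeslice()].
#' @param variant one of the three variant names.
#' @param importance_labels for the important variant: a data frame
#'   with `subject_cui`, `predicate`, `object_cui`, `label` columns
#'   (e.g. a labeled set or classifier predictions over the post
#'   triples).
#' @return An object of class `gold_standard` with the variant name and
#'   a de-duplicated `pairs` data frame.
#' @export
build_gold_standard <- function(post, variant = gold_variants,
                                importance_labels = NULL) {
  variant <- match.arg(variant)
  post <- as.data.frame(post)
  sel <- switch(variant,
    all_post_triples = post,
    post_abstract_triples = post[post$section == "abstract", , drop = FALSE],
    post_important_triples = {
      if (is.null(importance_labels))
        stop("importance_labels are required for the post_important_triples variant")
      imp <- importance_labels[importance_labels$label == "important", ,
                               drop = FALSE]
      keys <- triple_key(imp$subject_cui, imp$predicate, imp$object_cui)
      post[triple_key(post$subject_cui, post$predicate, post$object_cui)
           %in% keys, , drop = FALSE]
    })
  pairs <- unique(data.frame(source_cui = sel$subject_cui,
                             target_cui = sel$object_cui,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  structure(list(variant = variant, pairs = pairs), class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> variant=%s, %d concept pairs\n",
              x$variant, nrow(x$pairs)))
  invisible(x)
}

#' Precision of a CHKP set against a gold standard
#'
#' The fraction of proposed pairs found in the gold standard,
#' `|CHKP intersect gold| / |CHKP|`. Matching is on ordered
#' (source, target) pairs unless `unordered = TRUE`. Precision is
#' undefined for an empty CHKP set (an error, not 0).
#'
#' @param chkps a `chkp_set` from [extract_chkps()].
#' @param gold a [build_gold_standard()] object.
#' @param unordered also count a match when the reversed pair is in the
#'   gold standard.
#' @return Proportion in `[0, 1]`.
#' @export
precision <- function(chkps, gold, unordered = FALSE) {
  if (nrow(chkps) == 0L)
    stop_lbd("precision is undefined for an empty CHKP set",
             "lbd_empty_chkps")
  gk <- pair_key(gold$pairs$source_cui, gold$pairs$target_cui)
  hit <- pair_key(chkps$source_cui, chkps$target_cui) %in% gk
  if (unordered)
    hit <- hit | pair_key(chkps$target_cui, chkps$source_cui) %in% gk
  sum(hit) / nrow(chkps)
}

#' Timeslicing evaluation of a triple source
#'
#' Runs open discovery on the supplied pre-cutoff triples
#' ([build_graph()] then [extract_chkps()]) and scores the resulting
#' CHKPs against each requested gold-standard variant built from the
#' post-cutoff corpus. The report carries the total CHKP count, the
#' size of each gold standard, and per-variant precision both as a
#' proportion and as a percentage; it also retains the CHKPs absent
#' from every evaluated gold standard (the "as yet undiscovered"
#' candidates).
#'
#' @param pre_triples data frame of triples drawn from pre-cutoff
#'   publications (e.g. `distinct_triples(pre)` or its
#'   important-labeled subset).
#' @param post the post-cutoff corpus.
#' @param variants gold-standard variants to evaluate (default all
#'   three).
#' @param importance_labels passed to [build_gold_standard()] when the
#'   important variant is requested.
#' @param triples_source label naming the triple source in the report
#'   (e.g. `"all"` or `"important"`).
#' @return An object of class `lbd_eval_report`.
#' @export
evaluate <- function(pre_triples, post, variants = gold_variants,
                     importance_labels = NULL, triples_source = "triples") {
  graph <- build_graph(pre_triples)
  chkps <- extract_chkps(graph)
  golds <- lapply(variants, build_gold_standard, post = post,
                  importance_labels = importance_labels)
  names(golds) <- variants
  prec <- vapply(golds, function(g)
    if (nrow(chkps)) precision(chkps, g) else NA_real_, 0)
  sizes <- vapply(golds, function(g) nrow(g$pairs), 0L)
  in_any <- rep(FALSE, nrow(chkps))
  for (g in golds)
    in_any <- in_any | pair_key(chkps$source_cui, chkps$target_cui) %in%
      pair_key(g$pairs$source_cui, g$pairs$target_cui)
  structure(list(triples_source = triples_source,
                 n_triples = nrow(unique(as.data.frame(pre_triples))),
                 total_chkps = nrow(chkps),
                 precision = prec,
                 precision_percent = 100 * prec,
                 gold_sizes = sizes,
                 chkps = chkps,
                 undiscovered = chkps[!in_any, , drop = FALSE]),
            class = "lbd_eval_report")
}

#' @export
print.lbd_eval_report <- function(x, ...) {
  cat(sprintf("<lbd_eval_report> source=%s, %d triples -> %d CHKPs\n",
              x$triples_source, x$n_triples, x$total_chkps))
  for (v in names(x$precision)) {
    cat(sprintf("  %-24s gold size %6d  precision %.3f (%.1f%%)\n",
                v, x$gold_sizes[[v]], x$precision[[v]],
                x$precision_percent[[v]]))
  }
  cat(sprintf("  undiscovered CHKPs (absent from all golds): %d\n",
              nrow(x$undiscovered)))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per gold-standard variant with the CHKP count, gold size,
#' and precision as proportion and percentage.
#'
#' @param report an `lbd_eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("#triples_source\tgold_variant\ttotal_chkps\tgold_size\tprecision\tprecision_percent",
             vapply(names(report$precision), function(v)
               paste(report$triples_source, v, report$total_chkps,
                     report$gold_sizes[[v]], fmt_num(report$precision[[v]]),
                     fmt_num(report$precision_percent[[v]], 4), sep = "\t"),
               ""))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
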