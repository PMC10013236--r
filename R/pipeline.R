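#' Pipeline run configuration
#'
#' A single JSON-serializable document describing an end-to-end run:
#' label the post-cutoff corpus by triple similarity, train an
#' importance classifier on it, predict the importance of pre-cutoff
#' triples, perform open discovery on all pre-cutoff triples and on the
#' important subset, and evaluate both CHKP sets against the
#' gold-standard variants. Every random operation receives its seed
#' from the config, so a run reproduces bit-exactly from its persisted
#' config (up to the floating-point backend).
#'
#' Inputs come either from files (`predications`,
#' `concept_embeddings`, `predicate_embeddings`, `hierarchy`) or, when
#' `synthetic` is a list of [synthetic_spec()] arguments, from the
#' generator.
#'
#' @param cutoff timeslice cutoff date `D`.
#' @param hi,lo similarity-labeling thresholds (see
#'   [similarity_config()]).
#' @param classifier importance classifier to use: `"triple_lm"` (the
#'   masked triple language model with a fine-tuned head),
#'   `"feature"` (the halving-layer feature network), `"similarity"`
#'   (threshold labels themselves, available only when pre-cutoff
#'   documents have abstracts), or `"none"` (no importance filtering;
#'   the baseline).
#' @param seed master integer seed; stage seeds are derived from it.
#' @param synthetic optional list of [synthetic_spec()] arguments.
#' @param predications,concept_embeddings,predicate_embeddings,hierarchy
#'   optional input file paths (ignored when `synthetic` is given).
#' @param lm list of [triple_lm_config()] overrides.
#' @param feature list of [feature_model_config()] overrides.
#' @param out_dir optional artifact directory; when set, the config,
#'   intermediate TSVs, the CHKP exports, the report and a stage log
#'   are persisted there.
#' @return A `run_config` list (schema version 1).
#' @export
run_config <- function(cutoff = "2021-01-01", hi = 2.5, lo = 1.5,
                       classifier = c("triple_lm", "feature", "similarity",
                                      "none"),
                       seed = 1L, synthetic = NULL,
                       predications = NULL, concept_embeddings = NULL,
                       predicate_embeddings = NULL, hierarchy = NULL,
                       lm = list(), feature = list(), out_dir = NULL) {
  structure(list(schema_version = 1L, cutoff = as.character(cutoff),
                 hi = hi, lo = lo, classifier = match.arg(classifier),
                 seed = as.integer(seed), synthetic = synthetic,
                 predications = predications,
                 concept_embeddings = concept_embeddings,
                 predicate_embeddings = predicate_embeddings,
                 hierarchy = hierarchy, lm = lm, feature = feature,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if ((x$schema_version %||% 0) != 1L)
    stop("unsupported run_config schema version: ", x$schema_version)
  do.call(run_config, x[setdiff(names(x), "schema_version")])
}

stage_log <- function(con, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  message(sprintf("[%s] %s", stage, line))
  if (!is.null(con)) writeLines(line, con)
}

# Aggregate per-predication importance to the triple level: a triple is
# important when any of its occurrences is predicted important.
aggregate_triple_labels <- function(predications, labels) {
  key <- triple_key(predications$subject_cui, predications$predicate,
                    predications$object_cui)
  imp <- tapply(labels == "important", key, any)
  tri <- distinct_triples(predications)
  tri$label <- ifelse(imp[triple_key(tri$subject_cui, tri$predicate,
                                     tri$object_cui)],
                      "important", "not_important")
  tri
}

# Similarity-threshold labels at the triple level (importance = some
# occurrence scored >= hi against its document's abstract).
similarity_triple_labels <- function(corpus, stores, cfg) {
  lab <- build_training_set(corpus, stores$concepts, stores$predicates, cfg)
  aggregate_triple_labels(lab, lab$label)
}

#' Run the full discovery pipeline
#'
#' Executes label, train, predict, discover and evaluate in order (see
#' [run_config()]) and returns the two evaluation reports: the baseline
#' using all distinct pre-cutoff triples and the filtered run using
#' only triples predicted important. Stage counts (triples in, triples
#' important, CHKPs out) are logged as one JSON line per stage.
#'
#' @param config a [run_config()].
#' @param corpus,stores,hierarchy optional in-memory inputs (an
#'   [corpus()], a list with `concepts`/`predicates`
#'   [embedding_store()]s, and a parent--child data frame), taking
#'   precedence over the config's file paths.
#' @return A list of class `lbd_pipeline_result` with elements
#'   `report_all`, `report_important` (both [evaluate()] reports;
#'   `report_important` is `NULL` for `classifier = "none"`), `counts`,
#'   and `config`.
#' @export
run_pipeline <- function(config, corpus = NULL, stores = NULL,
                         hierarchy = NULL) {
  cfg_sim <- similarity_config(hi = config$hi, lo = config$lo)
  out_dir <- config$out_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.json"))
    log_con <- file(file.path(out_dir, "log.jsonl"), open = "wb")
    on.exit(close(log_con))
  }
  # --- inputs -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- do.call(synthetic_spec, config$synthetic)
    if (is.null(corpus)) corpus <- gen_corpus(spec)
    if (is.null(stores)) stores <- gen_embeddings(spec)
    if (is.null(hierarchy)) hierarchy <- gen_hierarchy(spec)
  } else {
    if (is.null(corpus)) {
      if (is.null(config$predications))
        stop("no corpus: supply `corpus`, config$predications or config$synthetic")
      corpus <- read_predications(config$predications)
    }
    if (is.null(stores)) {
      if (is.null(config$concept_embeddings) ||
          is.null(config$predicate_embeddings))
        stop("no embeddings: supply `stores` or embedding paths in the config")
      stores <- list(
        concepts = load_embeddings(config$concept_embeddings, "concept"),
        predicates = load_embeddings(config$predicate_embeddings, "predicate"))
    }
    if (is.null(hierarchy) && !is.null(config$hierarchy))
      hierarchy <- read_hierarchy(config$hierarchy)
  }
  slices <- timeslice(corpus, config$cutoff)
  pre_triples <- distinct_triples(slices$pre)
  stage_log(log_con, "timeslice", cutoff = config$cutoff,
            n_pre = nrow(slices$pre), n_post = nrow(slices$post),
            n_pre_triples = nrow(pre_triples))
  # --- label: similarity-threshold training set on the post slice ---
  labeled_post <- build_training_set(slices$post, stores$concepts,
                                     stores$predicates, cfg_sim)
  if (!is.null(out_dir))
    write_labeled_triples(labeled_post, file.path(out_dir, "labeled_post.tsv"))
  stage_log(log_con, "label", n_labeled = nrow(labeled_post),
            n_important = sum(labeled_post$label == "important"),
            n_not_important = sum(labeled_post$label == "not_important"),
            n_gap = sum(labeled_post$label == "discarded_gap"),
            n_docs_skipped = attr(labeled_post, "n_docs_skipped"))
  # --- train + predict importance of pre-cutoff triples -------------
  pre_importance <- post_importance <- NULL
  if (config$classifier == "triple_lm") {
    balanced <- balance_by_undersampling(labeled_post, config$seed)
    lm <- do.call(triple_lm_config, config$lm)
    lm <- train_triple_lm(distinct_triples(corpus), lm,
                          seed = config$seed + 1L)
    clf <- finetune_classifier(lm, balanced, seed = config$seed + 2L)
    stage_log(log_con, "train", classifier = "triple_lm",
              n_train = clf$n_train,
              final_lm_loss = lm$loss[length(lm$loss)])
    pre_importance <- cbind(pre_triples[, 1:3],
                            label = predict_triple_importance(
                              clf, pre_triples)$label)
    post_triples <- distinct_triples(slices$post)
    post_importance <- cbind(post_triples,
                             label = predict_triple_importance(
                               clf, post_triples)$label)
  } else if (config$classifier == "feature") {
    balanced <- balance_by_undersampling(labeled_post, config$seed)
    feats <- extract_features_corpus(balanced, hierarchy)
    fm <- train_feature_model(feats, do.call(feature_model_config,
                                             config$feature),
                              seed = config$seed + 1L)
    stage_log(log_con, "train", classifier = "feature",
              patterns = paste(names(fm$models), collapse = ","))
    pre_feats <- extract_features_corpus(slices$pre, hierarchy)
    pre_pred <- predict_importance_all(fm, pre_feats)
    pre_importance <- aggregate_triple_labels(slices$pre, pre_pred$label)
    post_feats <- extract_features_corpus(slices$post, hierarchy)
    post_pred <- predict_importance_all(fm, post_feats)
    post_importance <- aggregate_triple_labels(slices$post, post_pred$label)
  } else if (config$classifier == "similarity") {
    stage_log(log_con, "train", classifier = "similarity")
    pre_importance <- similarity_triple_labels(slices$pre, stores, cfg_sim)
    post_importance <- aggregate_triple_labels(labeled_post,
                                               labeled_post$label)
  } else {
    stage_log(log_con, "train", classifier = "none")
  }
  important_triples <- NULL
  if (!is.null(pre_importance)) {
    key <- triple_key(pre_importance$subject_cui, pre_importance$predicate,
                      pre_importance$object_cui)
    imp_key <- key[pre_importance$label == "important"]
    important_triples <- pre_triples[
      triple_key(pre_triples$subject_cui, pre_triples$predicate,
                 pre_triples$object_cui) %in% imp_key, , drop = FALSE]
    stage_log(log_con, "predict", n_pre_triples = nrow(pre_triples),
              n_important = nrow(important_triples))
  }
  # --- discover + evaluate ------------------------------------------
  variants <- if (is.null(post_importance))
    c("all_post_triples", "post_abstract_triples") else gold_variants
  report_all <- evaluate(pre_triples, slices$post, variants,
                         importance_labels = post_importance,
                         triples_source = "all")
  stage_log(log_con, "discover", source = "all",
            total_chkps = report_all$total_chkps)
  report_imp <- NULL
  if (!is.null(important_triples)) {
    report_imp <- evaluate(important_triples, slices$post, variants,
                           importance_labels = post_importance,
                           triples_source = "important")
    stage_log(log_con, "discover", source = "important",
              total_chkps = report_imp$total_chkps)
  }
  if (!is.null(out_dir)) {
    write_chkps(report_all$chkps, file.path(out_dir, "chkps_all.tsv"))
    if (!is.null(report_imp)) {
      write_chkps(report_imp$chkps, file.path(out_dir, "chkps_important.tsv"))
      write_chkps(report_imp$undiscovered,
                  file.path(out_dir, "chkps_undiscovered.tsv"))
    }
    con <- file(file.path(out_dir, "report.tsv"), open = "wb")
    writeLines(report_tsv_lines(report_all, report_imp), con, sep = "\n")
    close(con)
    jsonlite::write_json(report_json(report_all, report_imp),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(report_all = report_all, report_important = report_imp,
                 counts = list(n_pre_triples = nrow(pre_triples),
                               n_important = if (is.null(important_triples))
                                 NA_integer_ else nrow(important_triples)),
                 config = config),
            class = "lbd_pipeline_result")
}

report_tsv_lines <- function(report_all, report_imp) {
  header <- "#triples_source\tgold_variant\ttotal_chkps\tgold_size\tprecision\tprecision_percent"
  row <- function(r) vapply(names(r$precision), function(v)
    paste(r$triples_source, v, r$total_chkps, r$gold_sizes[[v]],
          fmt_num(r$precision[[v]]), fmt_num(r$precision_percent[[v]], 4),
          sep = "\t"), "")
  c(header, row(report_all), if (!is.null(report_imp)) row(report_imp))
}

report_json <- function(report_all, report_imp) {
  one <- function(r) list(triples_source = r$triples_source,
                          n_triples = r$n_triples,
                          total_chkps = r$total_chkps,
                          precision = as.list(r$precision),
                          precision_percent = as.list(r$precision_percent),
                          gold_sizes = as.list(r$gold_sizes))
  c(list(all = one(report_all)),
    if (!is.null(report_imp)) list(important = one(report_imp)))
}

#' @export
print.lbd_pipeline_result <- function(x, ...) {
  cat("<lbd_pipeline_result>\n")
  print(x$report_all)
  if (!is.null(x$report_important)) print(x$report_important)
  invisible(x)
}
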