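#' Feature-model configuration
#'
#' Architecture and training settings for the feature-based importance
#' classifier: a fully connected network whose hidden layer widths
#' halve at each successive layer, ReLU activations throughout, a
#' single sigmoid output unit, and binary cross-entropy loss. The
#' defaults are the best-performing settings for this model family:
#' depth 4, 200 training epochs, no dropout.
#'
#' @param depth number of hidden layers.
#' @param epochs training epochs (full batch).
#' @param dropout dropout probability on hidden activations, in `[0, 1)`.
#' @param first_layer_width width of the first hidden layer; successive
#'   layers halve (floored at 1).
#' @param learning_rate Adam step size.
#' @return A `feature_model_config` list.
#' @export
feature_model_config <- function(depth = 4L, epochs = 200L, dropout = 0,
                                 first_layer_width = 16L,
                                 learning_rate = 0.01) {
  stopifnot(depth >= 1L, epochs >= 1L, dropout >= 0, dropout < 1,
            first_layer_width >= 1L)
  structure(list(depth = as.integer(depth), epochs = as.integer(epochs),
                 dropout = dropout,
                 first_layer_width = as.integer(first_layer_width),
                 learning_rate = learning_rate),
            class = "feature_model_config")
}

halving_widths <- function(first, depth) {
  pmax(as.integer(first / 2^(seq_len(depth) - 1L)), 1L)
}

feature_design <- function(features, pattern, section_levels,
                           center = NULL, scale = NULL) {
  sec <- outer(features$section, section_levels, `==`) * 1
  colnames(sec) <- paste0("section_", section_levels)
  num_feats <- if (pattern == "none") character() else
    strsplit(pattern, "+", fixed = TRUE)[[1]]
  X <- sec
  if (length(num_feats)) {
    num <- as.matrix(features[, num_feats, drop = FALSE])
    storage.mode(num) <- "double"
    if (is.null(center)) {
      center <- colMeans(num)
      scale <- apply(num, 2, stats::sd)
      scale[!is.finite(scale) | scale == 0] <- 1
    }
    num <- sweep(sweep(num, 2, center, "-"), 2, scale, "/")
    X <- cbind(sec, num)
  }
  list(X = X, center = center, scale = scale)
}

#' Train the feature-based importance models
#'
#' Trains one halving-width network per availability pattern present in
#' the data (see [extract_features()]): since TextRank and the two
#' concept depths can be missing, a separate model is fitted for each
#' observed subset of available features, and at prediction time the
#' model using the most features applies. Patterns whose instances all
#' carry one class are skipped with a warning.
#'
#' @param data a feature data frame from [extract_features_corpus()]
#'   with a `label` column (`important` / `not_important`; gap
#'   instances are ignored).
#' @param config a [feature_model_config()].
#' @param seed integer seed controlling weight initialization (and
#'   dropout, if enabled).
#' @return An object of class `feature_importance_models`: one trained
#'   network per pattern plus the section one-hot levels.
#' @export
train_feature_model <- function(data, config = feature_model_config(),
                                seed = 1L) {
  data <- data[data$label %in% c("important", "not_important"), , drop = FALSE]
  if (!nrow(data)) stop_lbd("no labeled instances to train on",
                            "lbd_single_class")
  section_levels <- sort(unique(data$section))
  models <- list()
  for (pat in sort(unique(data$pattern))) {
    rows <- data[data$pattern == pat, , drop = FALSE]
    y <- as.integer(rows$label == "important")
    if (length(unique(y)) < 2L) {
      warning(sprintf("pattern '%s' has a single class; skipped", pat))
      next
    }
    des <- feature_design(rows, pat, section_levels)
    net <- mlp_train_binary(des$X, y,
                            hidden = halving_widths(config$first_layer_width,
                                                    config$depth),
                            epochs = config$epochs,
                            lr = config$learning_rate,
                            dropout = config$dropout, seed = seed)
    models[[pat]] <- list(pattern = pat, net = net,
                          center = des$center, scale = des$scale,
                          n_train = nrow(rows))
  }
  if (!length(models))
    stop_lbd("no availability pattern had both classes", "lbd_single_class")
  structure(list(models = models, section_levels = section_levels,
                 config = config),
            class = "feature_importance_models")
}

#' @export
print.feature_importance_models <- function(x, ...) {
  cat(sprintf("<feature_importance_models> %d pattern model(s): %s\n",
              length(x$models), paste(names(x$models), collapse = ", ")))
  invisible(x)
}

pattern_features <- function(pattern) {
  if (pattern == "none") character() else
    strsplit(pattern, "+", fixed = TRUE)[[1]]
}

#' Predict importance with the feature models
#'
#' Applies the missing-feature model-selection rule: among the trained
#' pattern models whose features are all available for the instance,
#' the one using the largest number of features is selected; ties are
#' broken by the lexicographically first pattern identifier. The chosen
#' network's sigmoid output is the importance probability; the binary
#' label thresholds it at 0.5.
#'
#' @param models a `feature_importance_models` object.
#' @param features one-row feature data frame from [extract_features()].
#' @return A list with `label` (`"important"` / `"not_important"`),
#'   `probability`, and `model_used` (the pattern identifier).
#' @export
predict_importance <- function(models, features) {
  avail <- feature_names[!is.na(unlist(features[1, feature_names]))]
  cand <- names(models$models)[vapply(names(models$models), function(p)
    all(pattern_features(p) %in% avail), NA)]
  if (!length(cand))
    stop_lbd("no trained model is applicable to the available features",
             "lbd_no_applicable_model")
  sizes <- lengths(lapply(cand, pattern_features))
  cand <- sort(cand[sizes == max(sizes)])
  pat <- cand[1]
  m <- models$models[[pat]]
  des <- feature_design(features, pat, models$section_levels,
                        center = m$center, scale = m$scale)
  p <- as.numeric(mlp_predict_binary(m$net, des$X))
  list(label = if (p > 0.5) "important" else "not_important",
       probability = p, model_used = pat)
}

#' Batch importance prediction with the feature models
#'
#' @param models a `feature_importance_models` object.
#' @param features feature data frame, one row per instance.
#' @return Data frame with `label`, `probability`, `model_used` per row.
#' @export
predict_importance_all <- function(models, features) {
  out <- lapply(seq_len(nrow(features)), function(i)
    predict_importance(models, features[i, , drop = FALSE]))
  data.frame(label = vapply(out, `[[`, "", "label"),
             probability = vapply(out, `[[`, 0, "probability"),
             model_used = vapply(out, `[[`, "", "model_used"),
             stringsAsFactors = FALSE)
}
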