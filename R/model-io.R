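#' Persist and restore importance models
#'
#' Writes a trained importance model (either kind) to a versioned
#' directory: `config.json` describes the model kind and its settings,
#' `weights.rds` holds the trained parameters. The directory is a
#' run-time artifact, not an exchange format.
#'
#' @param model a `feature_importance_models` or `triple_lm_classifier`
#'   object.
#' @param dir target directory (created if needed).
#' @return `load_importance_model()` returns the restored model.
#' @export
save_importance_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kind <- if (inherits(model, "feature_importance_models")) "feature"
  else if (inherits(model, "triple_lm_classifier")) "triple_lm"
  else stop("unknown model class: ", paste(class(model), collapse = "/"))
  meta <- list(format_version = 1L, kind = kind,
               settings = switch(kind,
                 feature = c(unclass(model$config),
                             list(patterns = names(model$models),
                                  section_levels = model$section_levels)),
                 triple_lm = c(unclass(model$lm$config),
                               list(vocab_size_realized =
                                      length(model$lm$vocab)))))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_importance_model
#' @export
load_importance_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"))
  if ((meta$format_version %||% 0) != 1L)
    stop("unsupported model format version")
  readRDS(file.path(dir, "weights.rds"))
}
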