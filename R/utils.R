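`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
triple_key <- function(subject_cui, predicate, object_cui) {
  paste(subject_cui, predicate, object_cui, sep = "\t")
}

pair_key <- function(source_cui, target_cui) {
  paste(source_cui, target_cui, sep = "\t")
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's RNG
# state.  All randomised operations in the package go through this so a
# run is a pure function of its seeds.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_lbd <- function(msg, class) {
  stop(structure(class = c(class, "lbd_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_iso_date <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(suppressWarnings(
    as.Date(x, format = "%Y-%m-%d")))
}

# Fixed-format numeric rendering used by all TSV writers, so that artifacts
# are byte-identical across reruns of the same configuration.
fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[is.na(x)] <- "-"
  out
}
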