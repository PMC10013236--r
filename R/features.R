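#' Concept-hierarchy depth
#'
#' The depth of a concept in a rooted hierarchy (shortest path from the
#' root, with the root at depth 0). Hierarchies are parent--child edge
#' tables, e.g. a subset of a thesaurus ISA taxonomy; in a tree each
#' concept has one parent so the depth is the number of steps to the
#' root.
#'
#' @param hierarchy data frame with columns `parent` and `child`.
#' @param cui concept identifier (vectorized).
#' @return Integer depth(s); `NA` for concepts absent from the
#'   hierarchy.
#' @export
cui_depth <- function(hierarchy, cui) {
  parent_of <- stats::setNames(hierarchy$parent, hierarchy$child)
  roots <- attr(hierarchy, "root") %||% setdiff(hierarchy$parent,
                                                hierarchy$child)
  one <- function(x) {
    if (x %in% roots) return(0L)
    d <- 0L
    limit <- length(parent_of) + 1L
    while (!is.na(parent_of[x])) {
      x <- unname(parent_of[x])
      d <- d + 1L
      if (d > limit) stop("cycle in concept hierarchy")
      if (x %in% roots) return(d)
    }
    NA_integer_
  }
  vapply(as.character(cui), one, 0L, USE.NAMES = FALSE)
}

#' Read / write a concept hierarchy
#'
#' Tab-separated `parent child` edge table with a `#` header line. The
#' root is the concept that appears as a parent but never as a child.
#'
#' @param path file path.
#' @return `read_hierarchy()` returns a parent--child data frame.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(parent = parts[, 1], child = parts[, 2],
             stringsAsFactors = FALSE)
}

#' @rdname read_hierarchy
#' @param hierarchy parent--child data frame.
#' @export
write_hierarchy <- function(hierarchy, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#parent\tchild",
               if (nrow(hierarchy))
                 paste(hierarchy$parent, hierarchy$child, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

feature_names <- c("textrank", "subject_depth", "object_depth")

availability_pattern <- function(has_textrank, has_sdepth, has_odepth) {
  present <- feature_names[c(has_textrank, has_sdepth, has_odepth)]
  if (!length(present)) "none" else paste(present, collapse = "+")
}

#' Extract classifier features for a predication
#'
#' The feature-based importance model uses features drawn from a
#' paper's full text: the section the triple appeared in (one-hot), the
#' TextRank score of the triple's sentence, and the hierarchy depths of
#' the two concepts. The latter three can be missing (no sentence
#' information, concept absent from the hierarchy); the subset that is
#' present is the predication's *availability pattern*, which selects
#' which trained model applies at prediction time.
#'
#' @param predication one-row corpus data frame (or list with the same
#'   fields).
#' @param hierarchy optional parent--child data frame for [cui_depth()].
#' @param textrank optional named score vector from [compute_textrank()]
#'   for the predication's document (names are 0-based sentence
#'   indices).
#' @return A one-row data frame with columns `section`, `textrank`,
#'   `subject_depth`, `object_depth`, `pattern`.
#' @export
extract_features <- function(predication, hierarchy = NULL, textrank = NULL) {
  tr <- NA_real_
  si <- predication$sentence_index
  if (!is.null(textrank) && length(si) && !is.na(si)) {
    v <- textrank[as.character(si)]
    if (length(v) == 1L && !is.na(v)) tr <- unname(v)
  }
  sd <- od <- NA_integer_
  if (!is.null(hierarchy)) {
    sd <- cui_depth(hierarchy, predication$subject_cui)
    od <- cui_depth(hierarchy, predication$object_cui)
  }
  data.frame(section = as.character(predication$section),
             textrank = tr, subject_depth = sd, object_depth = od,
             pattern = availability_pattern(!is.na(tr), !is.na(sd), !is.na(od)),
             stringsAsFactors = FALSE)
}

#' Extract features for every predication of a labeled set
#'
#' Computes TextRank per document from the available sentence texts
#' (whitespace-tokenized, one score per distinct `sentence_index`) and
#' applies [extract_features()] row-wise.
#'
#' @param predications a corpus or `labeled_triples` data frame.
#' @param hierarchy optional parent--child data frame.
#' @return A feature data frame, rows aligned with `predications`; the
#'   `label` column is carried through when present.
#' @export
extract_features_corpus <- function(predications, hierarchy = NULL) {
  df <- as.data.frame(predications)
  tr_by_doc <- list()
  for (doc in unique(df$doc_id)) {
    rows <- df[df$doc_id == doc & !is.na(df$sentence_index) &
                 !is.na(df$sentence_text), , drop = FALSE]
    if (!nrow(rows)) next
    rows <- rows[!duplicated(rows$sentence_index), , drop = FALSE]
    rows <- rows[order(rows$sentence_index), , drop = FALSE]
    toks <- strsplit(rows$sentence_text, "\\s+")
    sc <- compute_textrank(toks)
    names(sc) <- as.character(rows$sentence_index)
    tr_by_doc[[doc]] <- sc
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    extract_features(df[i, ], hierarchy, tr_by_doc[[df$doc_id[i]]])))
  if ("label" %in% names(df)) out$label <- df$label
  rownames(out) <- NULL
  out
}
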