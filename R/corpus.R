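#' Predication corpora
#'
#' A corpus is an ordered collection of predications: dated, sectioned
#' occurrences of subject--predicate--object (SPO) triples in documents,
#' the unit of record produced by biomedical relation extractors such as
#' SemRep. Concepts are UMLS-style concept unique identifiers (CUIs,
#' `C` followed by seven digits) and predicates are uppercase relation
#' tokens such as `TREATS` or `PROCESS_OF`.
#'
#' `corpus()` builds a corpus from its component vectors; `as_corpus()`
#' validates a data frame with the same columns. The `section` of each
#' predication is `"abstract"` or `"body"`; `sentence_index` and
#' `sentence_text` are optional (`NA` when the extractor did not supply
#' them).
#'
#' @param doc_id character vector of document identifiers.
#' @param date document dates, `Date` or ISO-8601 (`YYYY-MM-DD`) strings.
#' @param section `"abstract"` or `"body"` per predication.
#' @param subject_cui,predicate,object_cui the SPO triple fields.
#' @param sentence_index optional non-negative integer sentence position.
#' @param sentence_text optional sentence string.
#' @param validate_cuis if `TRUE`, require the `C[0-9]{7}` CUI format for
#'   subject and object identifiers.
#' @return An object of class `lbd_corpus` (a data frame with one row per
#'   predication).
#' @examples
#' co <- corpus(doc_id = "d1", date = "2020-06-01", section = "abstract",
#'              subject_cui = "C0011847", predicate = "PROCESS_OF",
#'              object_cui = "C0030705")
#' nrow(co)
#' @export
corpus <- function(doc_id = character(), date = as.Date(character()),
                   section = character(),
                   subject_cui = character(), predicate = character(),
                   object_cui = character(),
                   sentence_index = NA_integer_, sentence_text = NA_character_,
                   validate_cuis = FALSE) {
  n <- max(length(doc_id), length(date), length(section), length(subject_cui))
  if (n == 0L) {
    df <- data.frame(doc_id = character(), date = as.Date(character()),
                     section = character(), sentence_index = integer(),
                     sentence_text = character(), subject_cui = character(),
                     predicate = character(), object_cui = character(),
                     stringsAsFactors = FALSE)
    return(as_corpus(df))
  }
  df <- data.frame(doc_id = rep_len(as.character(doc_id), n),
                   date = rep_len(as.Date(date), n),
                   section = rep_len(as.character(section), n),
                   sentence_index = rep_len(as.integer(sentence_index), n),
                   sentence_text = rep_len(as.character(sentence_text), n),
                   subject_cui = rep_len(as.character(subject_cui), n),
                   predicate = rep_len(as.character(predicate), n),
                   object_cui = rep_len(as.character(object_cui), n),
                   stringsAsFactors = FALSE)
  as_corpus(df, validate_cuis = validate_cuis)
}

#' @rdname corpus
#' @param x a data frame with the corpus columns.
#' @export
as_corpus <- function(x, validate_cuis = FALSE) {
  cols <- c("doc_id", "date", "section", "sentence_index", "sentence_text",
            "subject_cui", "predicate", "object_cui")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols))
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "))
  x <- x[, cols]
  x$date <- as.Date(x$date)
  x$sentence_index <- as.integer(x$sentence_index)
  bad <- !x$section %in% c("abstract", "body")
  if (any(bad))
    stop_lbd(sprintf("invalid section value(s): %s (row %s)",
                     paste(unique(x$section[bad]), collapse = ", "),
                     which(bad)[1]), "lbd_bad_section")
  if (any(is.na(x$date)))
    stop_lbd(sprintf("unparseable date at row %s", which(is.na(x$date))[1]),
             "lbd_bad_date")
  ok_pred <- grepl("^[A-Z][A-Z0-9_]*$", x$predicate)
  if (!all(ok_pred))
    stop_lbd(sprintf("invalid predicate '%s' at row %d (expected uppercase token)",
                     x$predicate[!ok_pred][1], which(!ok_pred)[1]),
             "lbd_bad_predicate")
  if (validate_cuis) {
    bad_cui <- !grepl("^C[0-9]{7}$", x$subject_cui) |
      !grepl("^C[0-9]{7}$", x$object_cui)
    if (any(bad_cui))
      stop_lbd(sprintf("invalid CUI at row %d (CUIs have the form C followed by 7 digits)",
                       which(bad_cui)[1]), "lbd_bad_cui")
  }
  rownames(x) <- NULL
  class(x) <- c("lbd_corpus", "data.frame")
  x
}

#' @export
print.lbd_corpus <- function(x, ...) {
  cat(sprintf("<lbd_corpus> %d predications, %d documents, %d distinct triples\n",
              nrow(x), length(unique(x$doc_id)), nrow(distinct_triples(x))))
  if (nrow(x)) {
    cat(sprintf("  dates %s .. %s; sections: %s\n",
                min(x$date), max(x$date),
                paste(names(table(x$section)), table(x$section),
                      sep = "=", collapse = ", ")))
    print(utils::head(as.data.frame(x), 5L))
    if (nrow(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

pred_columns <- c("doc_id", "date", "section", "sentence_index",
                  "sentence_text", "subject_cui", "predicate", "object_cui")

#' Read a predication file
#'
#' Reads the tab-separated predication dialect used throughout the
#' package: one header line starting with `#`, then one predication per
#' line with columns `doc_id`, `date`, `section`, `sentence_index`,
#' `sentence_text`, `subject_cui`, `predicate`, `object_cui`, with `-`
#' as the missing-value token. Dates must be ISO-8601 and `section` must
#' be `abstract` or `body`; offending lines are reported with their line
#' number.
#'
#' @param path path to a predication TSV file.
#' @param validate_cuis require the `C[0-9]{7}` identifier format
#'   (default `FALSE`, so synthetic identifiers are accepted).
#' @return An [corpus()] object.
#' @seealso [write_predications()], [filter_corpus()], [distinct_triples()]
#' @export
read_predications <- function(path, validate_cuis = FALSE) {
  if (!file.exists(path)) stop("predication file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(corpus())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 7L))
    stop_lbd(sprintf("line %d: expected >= 7 tab-separated fields, got %d",
                     line_no[nf < 7L][1], nf[nf < 7L][1]), "lbd_malformed_line")
  # sentence_text may legitimately be empty; pad 7-field lines
  parts[nf == 7L] <- lapply(parts[nf == 7L], function(p) append(p, "", after = 4))
  m <- do.call(rbind, lapply(parts, `[`, 1:8))
  m[m == "-"] <- NA
  bad_date <- !is_iso_date(m[, 2])
  if (any(bad_date))
    stop_lbd(sprintf("line %d: unparseable date '%s' (expected YYYY-MM-DD)",
                     line_no[bad_date][1], m[bad_date, 2][1]), "lbd_bad_date")
  bad_sec <- !m[, 3] %in% c("abstract", "body")
  if (any(bad_sec))
    stop_lbd(sprintf("line %d: invalid section '%s' (expected abstract|body)",
                     line_no[bad_sec][1], m[bad_sec, 3][1]), "lbd_bad_section")
  df <- data.frame(doc_id = m[, 1], date = as.Date(m[, 2]), section = m[, 3],
                   sentence_index = as.integer(m[, 4]), sentence_text = m[, 5],
                   subject_cui = m[, 6], predicate = m[, 7], object_cui = m[, 8],
                   stringsAsFactors = FALSE)
  tryCatch(as_corpus(df, validate_cuis = validate_cuis),
           lbd_bad_cui = function(e) stop_lbd(
             sub("row", "data line", conditionMessage(e)), "lbd_bad_cui"))
}

#' Write a predication file
#'
#' Writes a corpus in the dialect read by [read_predications()]. Missing
#' optional fields are written as `-`. A write--read round trip
#' reproduces the corpus field by field, and writing the re-read corpus
#' again is byte-identical.
#'
#' @param corpus an [corpus()] object.
#' @param path output path.
#' @export
write_predications <- function(corpus, path) {
  corpus <- as_corpus(corpus)
  header <- paste0("#", paste(pred_columns, collapse = "\t"))
  field <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "-"
    x
  }
  body <- if (nrow(corpus)) {
    paste(field(corpus$doc_id), format(corpus$date, "%Y-%m-%d"),
          field(corpus$section), field(corpus$sentence_index),
          field(corpus$sentence_text), field(corpus$subject_cui),
          field(corpus$predicate), field(corpus$object_cui), sep = "\t")
  } else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Filter a corpus by section and/or time slice
#'
#' Timeslicing convention: a predication is "pre" a cutoff date `D` when
#' its date is strictly before `D`, and "post" when its date is on or
#' after `D`. `filter_corpus(before = D)` and
#' `filter_corpus(on_or_after = D)` therefore partition a corpus with no
#' overlap.
#'
#' @param corpus an [corpus()] object.
#' @param section optional, keep only `"abstract"` or `"body"`.
#' @param before optional date; keep predications dated strictly earlier.
#' @param on_or_after optional date; keep predications dated on or later.
#' @return The filtered corpus, original order preserved.
#' @export
filter_corpus <- function(corpus, section = NULL, before = NULL,
                          on_or_after = NULL) {
  corpus <- as_corpus(corpus)
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(section)) {
    section <- match.arg(section, c("abstract", "body"))
    keep <- keep & corpus$section == section
  }
  if (!is.null(before)) keep <- keep & corpus$date < as.Date(before)
  if (!is.null(on_or_after)) keep <- keep & corpus$date >= as.Date(on_or_after)
  as_corpus(corpus[keep, , drop = FALSE])
}

#' Distinct SPO triples of a corpus
#'
#' Projects a corpus onto its set of distinct
#' (subject, predicate, object) triples, discarding document metadata.
#'
#' @param corpus an [corpus()] object, or any data frame with
#'   `subject_cui`, `predicate`, `object_cui` columns.
#' @return A data frame with one row per distinct triple, in first-seen
#'   order.
#' @export
distinct_triples <- function(corpus) {
  df <- as.data.frame(corpus)[, c("subject_cui", "predicate", "object_cui")]
  df <- df[!duplicated(triple_key(df$subject_cui, df$predicate, df$object_cui)),
           , drop = FALSE]
  rownames(df) <- NULL
  df
}
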