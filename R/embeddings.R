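#' Embedding stores
#'
#' An embedding store maps keys (concept identifiers or predicate
#' tokens) to fixed-dimension real vectors, the representation used by
#' the triple-similarity measure: concept pairs are compared with
#' concept embeddings (cui2vec-style) and predicates with word
#' embeddings (GloVe-style). Stores are read from word2vec text format:
#' one key per line followed by its components, with an optional
#' `count dimension` header line that is auto-detected.
#'
#' @param vectors a numeric matrix with one row per key; row names are
#'   the keys.
#' @param kind `"concept"` or `"predicate"`.
#' @return An object of class `embedding_store`.
#' @examples
#' st <- embedding_store(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'                              dimnames = list(c("C0000001", "C0000002"))),
#'                       kind = "concept")
#' embedding_dim(st)
#' @export
embedding_store <- function(vectors, kind = c("concept", "predicate")) {
  kind <- match.arg(kind)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (is.null(rownames(vectors))) stop("embedding matrix must have row names")
  zero <- rowSums(vectors != 0) == 0
  if (any(zero))
    stop_lbd(paste0("all-zero embedding vector for key(s): ",
                    paste(utils::head(rownames(vectors)[zero], 3), collapse = ", ")),
             "lbd_zero_vector")
  structure(list(vectors = vectors, kind = kind,
                 dimension = ncol(vectors)),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat(sprintf("<embedding_store> kind=%s, %d keys, dimension %d\n",
              x$kind, nrow(x$vectors), x$dimension))
  invisible(x)
}

#' @rdname embedding_store
#' @param store an `embedding_store`.
#' @export
embedding_dim <- function(store) store$dimension

#' @rdname embedding_store
#' @export
embedding_keys <- function(store) rownames(store$vectors)

#' Load embeddings from word2vec text format
#'
#' Each line holds a key followed by whitespace-separated real
#' components. A first line of exactly two integers is treated as the
#' word2vec `count dimension` header and skipped. All vectors must share
#' one dimension and no vector may be all-zero; violations are fatal
#' with the offending line number. Duplicate keys keep the last
#' occurrence, with a warning.
#'
#' @param path path to the embedding text file.
#' @param kind `"concept"` or `"predicate"`.
#' @return An [embedding_store()].
#' @export
load_embeddings <- function(path, kind = c("concept", "predicate")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty embedding file: ", path)
  offset <- 0L
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2L && all(grepl("^[0-9]+$", first))) offset <- 1L
  lines <- lines[(offset + 1L):length(lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(parts, `[`, "", 1L)
  vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1L])))
  dims <- lengths(vals)
  if (any(dims < 1L))
    stop_lbd(sprintf("line %d: key '%s' has no vector components",
                     which(dims < 1L)[1] + offset, keys[dims < 1L][1]),
             "lbd_bad_embedding_line")
  if (length(unique(dims)) > 1L) {
    bad <- which(dims != dims[1])[1]
    stop_lbd(sprintf("line %d: inconsistent dimension %d (expected %d)",
                     bad + offset, dims[bad], dims[1]), "lbd_dim_mismatch")
  }
  nas <- vapply(vals, function(v) anyNA(v), NA)
  if (any(nas))
    stop_lbd(sprintf("line %d: non-numeric vector component",
                     which(nas)[1] + offset), "lbd_bad_embedding_line")
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    warning(sprintf("duplicate embedding key(s) (%s); keeping the last occurrence",
                    paste(utils::head(dup, 3), collapse = ", ")))
    last <- !duplicated(keys, fromLast = TRUE)
    keys <- keys[last]
    vals <- vals[last]
  }
  m <- do.call(rbind, vals)
  rownames(m) <- keys
  zero <- rowSums(m != 0) == 0
  if (any(zero))
    stop_lbd(sprintf("all-zero vector for key '%s'", keys[zero][1]),
             "lbd_zero_vector")
  embedding_store(m, kind)
}

#' Save embeddings in word2vec text format
#'
#' Writes `count dimension` header plus one `key components...` line per
#' key. Components are written with enough digits that a save--load
#' round trip agrees within 1e-6 per component.
#'
#' @param store an [embedding_store()].
#' @param path output path.
#' @export
save_embeddings <- function(store, path) {
  m <- store$vectors
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(nrow(m), ncol(m)),
               paste(rownames(m),
                     apply(m, 1, function(v)
                       paste(sprintf("%.8g", v), collapse = " ")))),
             con, sep = "\n")
  invisible(path)
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`, in `[-1, 1]`. Both vectors must be nonzero
#' and of equal length.
#'
#' @param u,v numeric vectors.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("cosine: vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_lbd("cosine undefined for a zero-norm vector", "lbd_zero_vector")
  if (all(u == v)) return(1)  # self-similarity is exactly 1
  # clip rounding spill so the result is always inside [-1, 1]
  min(max(sum(u * v) / (nu * nv), -1), 1)
}

#' Look up a concept vector
#'
#' @param store a concept [embedding_store()].
#' @param cui concept identifier.
#' @return The stored vector; signals an error of class
#'   `lbd_missing_embedding` when the key is absent.
#' @export
concept_vector <- function(store, cui) {
  i <- match(cui, rownames(store$vectors))
  if (is.na(i))
    stop_lbd(paste0("no embedding for concept ", cui), "lbd_missing_embedding")
  store$vectors[i, ]
}

#' Look up or compose a predicate vector
#'
#' Predicates are matched directly against the store; a multi-token
#' predicate absent from the store (e.g. `PROCESS_OF` against a word
#' embedding store) falls back to the componentwise mean of the vectors
#' of its underscore-split, lower-cased tokens that are present. If no
#' token resolves, an error of class `lbd_missing_embedding` is
#' signalled.
#'
#' @param store a predicate [embedding_store()].
#' @param predicate relation token, e.g. `"TREATS"`.
#' @return A vector of length `embedding_dim(store)`.
#' @export
predicate_vector <- function(store, predicate) {
  keys <- rownames(store$vectors)
  i <- match(predicate, keys)
  if (!is.na(i)) return(store$vectors[i, ])
  toks <- tolower(strsplit(predicate, "_", fixed = TRUE)[[1]])
  hit <- match(toks, keys)
  hit <- hit[!is.na(hit)]
  if (!length(hit))
    stop_lbd(paste0("no embedding for predicate ", predicate,
                    " or any of its tokens"), "lbd_missing_embedding")
  colMeans(store$vectors[hit, , drop = FALSE])
}
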