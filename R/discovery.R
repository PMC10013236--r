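#' Knowledge graph over concept identifiers
#'
#' The A--B--C discovery model works on a directed graph whose vertices
#' are concept identifiers (CUIs) and whose edges record that at least
#' one SPO triple relates subject to object; predicates are ignored and
#' duplicate edges collapse, so the adjacency matrix is binary. The
#' vertex order is the sorted order of the identifiers, which fixes
#' matrix indices across runs.
#'
#' @param triples data frame with `subject_cui` and `object_cui`
#'   columns (a corpus or distinct-triple table).
#' @return An object of class `knowledge_graph` with sorted `vertices`
#'   and a sparse binary `adjacency` matrix.
#' @export
build_graph <- function(triples) {
  df <- as.data.frame(triples)
  verts <- sort(unique(c(df$subject_cui, df$object_cui)))
  if (!length(verts)) {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), dims = c(0, 0))
    return(structure(list(vertices = character(), adjacency = A),
                     class = "knowledge_graph"))
  }
  i <- match(df$subject_cui, verts)
  j <- match(df$object_cui, verts)
  keep <- !duplicated(paste(i, j))
  A <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(verts), length(verts)),
                            dimnames = list(verts, verts))
  structure(list(vertices = verts, adjacency = A), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  ne <- length(x$adjacency@x)
  nv <- length(x$vertices)
  cat(sprintf("<knowledge_graph> %d vertices, %d directed edges", nv, ne))
  if (nv) cat(sprintf(", mean out-degree %.3f", ne / nv))
  cat("\n")
  invisible(x)
}

#' Square the adjacency matrix
#'
#' For a binary adjacency matrix `A`, entry `(i, j)` of `A^2` counts
#' the walks of length two from vertex `i` to vertex `j` -- the number
#' of linking terms `B` with edges `i -> B -> j`. Computed sparsely.
#'
#' @param graph a [build_graph()] object.
#' @return Sparse integer-valued matrix `A^2`.
#' @export
square_adjacency <- function(graph) {
  A <- graph$adjacency
  Matrix::drop0(A %*% A)
}

#' Extract candidate hidden knowledge pairs (CHKPs)
#'
#' Open discovery under the A--B--C model: a pair `(A, C)` is a CHKP
#' when at least one two-step path `A -> B -> C` exists
#' (`A^2[A, C] > 0`) but the direct edge does not (`A[A, C] = 0`).
#' Self-pairs are excluded. Directionality follows the matrix
#' condition: a known reverse edge `C -> A` does not suppress the CHKP
#' `(A, C)` unless `suppress_symmetric` is set.
#'
#' @param graph a [build_graph()] object.
#' @param suppress_symmetric also drop pairs whose reverse edge is
#'   known (default `FALSE`).
#' @return An object of class `chkp_set`: a data frame with
#'   `source_cui`, `target_cui`, `linking_count` (the `A^2` entry),
#'   sorted by descending linking count then lexicographically.
#' @export
extract_chkps <- function(graph, suppress_symmetric = FALSE) {
  S <- square_adjacency(graph)
  A <- graph$adjacency
  idx <- Matrix::summary(S)
  keep <- idx$i != idx$j
  if (any(keep)) {
    known <- as.vector(A[cbind(idx$i[keep], idx$j[keep])]) != 0
    if (suppress_symmetric)
      known <- known | as.vector(A[cbind(idx$j[keep], idx$i[keep])]) != 0
    sel <- which(keep)[!known]
  } else sel <- integer()
  out <- data.frame(source_cui = graph$vertices[idx$i[sel]],
                    target_cui = graph$vertices[idx$j[sel]],
                    linking_count = as.integer(idx$x[sel]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$linking_count, out$source_cui, out$target_cui), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chkp_set", "data.frame")
  out
}

#' @export
print.chkp_set <- function(x, ...) {
  cat(sprintf("<chkp_set> %d candidate hidden knowledge pairs\n", nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Linking terms of a concept pair (closed discovery)
#'
#' All concepts `B` with edges `source -> B` and `B -> target`, i.e.
#' the terms that would confirm a suspected connection between the two
#' concepts.
#'
#' @param graph a [build_graph()] object.
#' @param source,target concept identifiers present in the graph.
#' @return Character vector of linking concepts (possibly empty).
#' @export
linking_terms <- function(graph, source, target) {
  i <- match(source, graph$vertices)
  j <- match(target, graph$vertices)
  if (is.na(i)) stop("unknown vertex: ", source)
  if (is.na(j)) stop("unknown vertex: ", target)
  A <- graph$adjacency
  out_nb <- which(A[i, ] != 0)
  in_nb <- which(A[, j] != 0)
  graph$vertices[intersect(out_nb, in_nb)]
}

#' Write a CHKP set as TSV
#'
#' Columns `source_cui`, `target_cui`, `linking_count`, in the sorted
#' order produced by [extract_chkps()].
#'
#' @param chkps a `chkp_set`.
#' @param path output path.
#' @export
write_chkps <- function(chkps, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#source_cui\ttarget_cui\tlinking_count",
               if (nrow(chkps))
                 paste(chkps$source_cui, chkps$target_cui,
                       chkps$linking_count, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}
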