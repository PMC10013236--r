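#' Synthetic-corpus specification
#'
#' Describes a synthetic corpus of dated documents with planted
#' importance structure and planted hidden knowledge, used to exercise
#' every pipeline stage without external data. Each document carries
#' *novel-contribution* triples (appearing in both its abstract and its
#' body), *background-knowledge* triples (body only, drawn from a
#' shared high-document-frequency pool), and optionally *noise*
#' triples whose similarity scores fall inside the labeling gap.
#' Hidden-knowledge structure is planted as concept chains
#' `A -> B -> C`: the edges `A -> B` and `B -> C` are placed in
#' documents dated before the cutoff and the edge `A -> C` in a
#' document dated on or after it, so open discovery on the pre-cutoff
#' slice should propose exactly the pairs `(A, C)`.
#'
#' Concept embeddings are constructed so the labels are separable by
#' orthogonality rather than by margin tuning: concepts and predicates
#' used by novel triples occupy one coordinate block and
#' background-triple concepts and predicates the complementary block,
#' so a background body triple has clamped similarity exactly 0 against
#' every abstract triple while a novel body triple (copied verbatim
#' from the abstract) scores exactly 3. Noise triples replace the
#' concepts of a novel triple with mixed-profile variants at cosine
#' `1/sqrt(2)` to the original, scoring `1 + sqrt(2)` (about 2.414),
#' inside the default (1.5, 2.5) gap.
#'
#' Documents straddle the cutoff: half are dated uniformly within
#' `pre_window_days` before it and half within `post_window_days` on or
#' after it (mirroring a training window such as the roughly three
#' months after a 2021-01-01 cutoff).
#'
#' @param n_docs number of documents.
#' @param cutoff cutoff date `D`.
#' @param n_concepts total number of concepts (identifiers `C0000001`
#'   onward); partitioned internally into a hierarchy root, planted
#'   concepts, novel subject/object pools, and background concepts.
#' @param embedding_dim embedding dimension (>= 2; split into the two
#'   orthogonal blocks).
#' @param novel_per_doc novel-contribution triples per document.
#' @param background_pool size of the shared background-triple pool
#'   (realized as a concept path `b1 -> b2 -> ...`, so background
#'   triples chain across documents).
#' @param background_per_doc background triples sampled into each
#'   document's body.
#' @param planted_hidden number of planted `(A, B, C)` hidden-knowledge
#'   chains.
#' @param noise_rate per-novel-triple probability of emitting a gap
#'   noise triple into the body.
#' @param seed integer seed; generation is a pure function of the spec.
#' @param pre_window_days,post_window_days widths of the date windows
#'   around the cutoff.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_docs = 60L, cutoff = "2021-01-01",
                           n_concepts = 60L, embedding_dim = 16L,
                           novel_per_doc = 2L, background_pool = 12L,
                           background_per_doc = 4L, planted_hidden = 2L,
                           noise_rate = 0, seed = 1L,
                           pre_window_days = 365L, post_window_days = 88L) {
  spec <- structure(list(
    n_docs = as.integer(n_docs), cutoff = as.Date(cutoff),
    n_concepts = as.integer(n_concepts),
    embedding_dim = as.integer(embedding_dim),
    novel_per_doc = as.integer(novel_per_doc),
    background_pool = as.integer(background_pool),
    background_per_doc = as.integer(background_per_doc),
    planted_hidden = as.integer(planted_hidden),
    noise_rate = noise_rate, seed = as.integer(seed),
    pre_window_days = as.integer(pre_window_days),
    post_window_days = as.integer(post_window_days)), class = "synthetic_spec")
  stopifnot(spec$n_docs >= 1L, spec$embedding_dim >= 2L,
            spec$novel_per_doc >= 1L, spec$background_pool >= 1L,
            spec$noise_rate >= 0, spec$noise_rate <= 1)
  layout <- synthetic_layout(spec)   # validates concept budget
  stopifnot(nrow(layout$concepts) == spec$n_concepts)
  spec
}

cui_name <- function(i) sprintf("C%07d", i)

novel_predicates <- c("TREATS", "CAUSES", "INHIBITS", "PREVENTS",
                      "STIMULATES", "DISRUPTS", "AUGMENTS", "PRODUCES")
background_predicates <- c("ISA", "PROCESS_OF", "LOCATION_OF", "PART_OF",
                           "COEXISTS_WITH", "AFFECTS")

# Deterministic allocation of the concept budget into roles.  Only the
# planted chains A -> B -> C create two-step walks among novel-role
# edges (novel subjects never occur as objects and vice versa), and the
# background pool is a path b1 -> b2 -> ... that chains by design.
synthetic_layout <- function(spec) {
  n_bg <- spec$background_pool + 1L
  fixed <- 1L + 3L * spec$planted_hidden + n_bg
  r <- spec$n_concepts - fixed
  if (r < 2L)
    stop(sprintf(paste0("inconsistent spec: %d concepts cannot hold the root, ",
                        "%d planted chain(s) and a background pool of %d ",
                        "(need at least %d + 2)"),
                 spec$n_concepts, spec$planted_hidden, spec$background_pool,
                 fixed))
  ids <- cui_name(seq_len(spec$n_concepts))
  root <- ids[1L]
  k <- 1L
  take <- function(n) {
    out <- ids[k + seq_len(n)]
    k <<- k + n
    out
  }
  planted_cuis <- take(3L * spec$planted_hidden)
  planted <- if (spec$planted_hidden > 0L) {
    m <- matrix(planted_cuis, ncol = 3L, byrow = TRUE)
    data.frame(a = m[, 1], b = m[, 2], c = m[, 3], stringsAsFactors = FALSE)
  } else data.frame(a = character(), b = character(), c = character())
  background <- take(n_bg)
  novel_subjects <- take(ceiling(r / 2))
  novel_objects <- take(r - ceiling(r / 2))
  pool <- data.frame(
    subject_cui = background[seq_len(spec$background_pool)],
    predicate = background_predicates[
      (seq_len(spec$background_pool) - 1L) %% length(background_predicates) + 1L],
    object_cui = background[seq_len(spec$background_pool) + 1L],
    stringsAsFactors = FALSE)
  novel_role <- c(root, planted_cuis, novel_subjects, novel_objects)
  concepts <- data.frame(
    cui = ids,
    role = c("root", rep("planted", length(planted_cuis)),
             rep("background", n_bg),
             rep("novel_subject", length(novel_subjects)),
             rep("novel_object", length(novel_objects))),
    block = ifelse(ids %in% novel_role, "novel", "background"),
    stringsAsFactors = FALSE)
  list(root = root, planted = planted, background = background,
       novel_subjects = novel_subjects, novel_objects = novel_objects,
       pool = pool, concepts = concepts)
}

#' Planted hidden-knowledge chains of a spec
#'
#' @param spec a [synthetic_spec()].
#' @return Data frame with columns `a`, `b`, `c`: the concepts of each
#'   planted chain. The expected CHKPs of the pre-cutoff slice are the
#'   `(a, c)` pairs.
#' @export
planted_pairs <- function(spec) synthetic_layout(spec)$planted

unit_block_vector <- function(dim, block_cols) {
  v <- numeric(dim)
  v[block_cols] <- stats::rnorm(length(block_cols))
  v / sqrt(sum(v^2))
}

#' Generate the synthetic embedding stores
#'
#' Concept and predicate stores with unit-norm vectors in two
#' orthogonal coordinate blocks (see [synthetic_spec()]): concepts and
#' predicates in novel roles occupy the first block, background ones
#' the second, so every novel/background cosine is exactly 0. When
#' `noise_rate > 0`, one mixed-profile noise variant per novel-pool
#' concept is appended (cosine `1/sqrt(2)` to its source concept).
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `concepts` and `predicates`, both
#'   [embedding_store()] objects.
#' @export
gen_embeddings <- function(spec) {
  layout <- synthetic_layout(spec)
  d <- spec$embedding_dim
  blk1 <- seq_len(ceiling(d / 2))
  blk2 <- setdiff(seq_len(d), blk1)
  if (!length(blk2)) { blk1 <- 1L; blk2 <- 2L }  # dim 2 edge case
  with_local_seed(spec$seed, {
    cm <- t(vapply(seq_len(nrow(layout$concepts)), function(i)
      unit_block_vector(d, if (layout$concepts$block[i] == "novel") blk1
                        else blk2), numeric(d)))
    rownames(cm) <- layout$concepts$cui
    if (spec$noise_rate > 0) {
      src <- c(layout$novel_subjects, layout$novel_objects)
      noise <- t(vapply(src, function(s) {
        w <- unit_block_vector(d, blk2)
        v <- cm[s, ] + w
        v / sqrt(sum(v^2))
      }, numeric(d)))
      rownames(noise) <- noise_variant(src)
      cm <- rbind(cm, noise)
    }
    pm <- t(vapply(seq_along(c(novel_predicates, background_predicates)),
                   function(i)
                     unit_block_vector(d, if (i <= length(novel_predicates))
                       blk1 else blk2), numeric(d)))
    rownames(pm) <- c(novel_predicates, background_predicates)
    list(concepts = embedding_store(cm, "concept"),
         predicates = embedding_store(pm, "predicate"))
  })
}

# Noise variants reuse the identifier space above the regular concepts.
noise_variant <- function(cui) {
  cui_name(9000000L + as.integer(sub("^C", "", cui)))
}

#' Generate the synthetic corpus
#'
#' Realizes the spec as a predication corpus: per document,
#' `novel_per_doc` novel triples in abstract and body, background pool
#' draws in the body, planted chains placed pre/post cutoff, and
#' optional gap-noise triples (see [synthetic_spec()]). Each
#' predication carries a sentence index and a sentence text (the triple
#' tokens), so TextRank and full feature extraction are exercised.
#'
#' @param spec a [synthetic_spec()].
#' @return An [corpus()] with attribute `triple_roles`, a data frame
#'   mapping each distinct generated triple to its planted role
#'   (`novel`, `background`, `noise`, `planted_ab`, `planted_bc`,
#'   `planted_ac`).
#' @export
gen_corpus <- function(spec) {
  layout <- synthetic_layout(spec)
  n_pre <- ceiling(spec$n_docs / 2)
  n_post <- spec$n_docs - n_pre
  if (spec$planted_hidden > 0L && n_post < 1L)
    stop("inconsistent spec: planted chains require at least one post-cutoff document")
  with_local_seed(spec$seed + 1L, {
    dates <- c(spec$cutoff - sample.int(spec$pre_window_days, n_pre,
                                        replace = TRUE),
               spec$cutoff + sample.int(spec$post_window_days, n_post,
                                        replace = TRUE) - 1L)
    doc_ids <- sprintf("doc%04d", seq_len(spec$n_docs))
    rows <- list()
    roles <- list()
    add <- function(doc, date, section, si, tri, role) {
      rows[[length(rows) + 1L]] <<- data.frame(
        doc_id = doc, date = date, section = section,
        sentence_index = si,
        sentence_text = paste(tri[1], tri[2], tri[3]),
        subject_cui = tri[1], predicate = tri[2], object_cui = tri[3],
        stringsAsFactors = FALSE)
      roles[[length(roles) + 1L]] <<- data.frame(
        subject_cui = tri[1], predicate = tri[2], object_cui = tri[3],
        role = role, stringsAsFactors = FALSE)
    }
    # planted chain placement
    planted_at <- list()
    if (spec$planted_hidden > 0L) {
      for (i in seq_len(spec$planted_hidden)) {
        pre_docs <- sample.int(n_pre, 2L, replace = n_pre < 2L)
        post_doc <- n_pre + sample.int(n_post, 1L)
        p <- layout$planted[i, ]
        rel <- novel_predicates[(i - 1L) %% length(novel_predicates) + 1L]
        planted_at[[length(planted_at) + 1L]] <- list(
          doc = pre_docs[1], tri = c(p$a, rel, p$b), role = "planted_ab")
        planted_at[[length(planted_at) + 1L]] <- list(
          doc = pre_docs[2], tri = c(p$b, rel, p$c), role = "planted_bc")
        planted_at[[length(planted_at) + 1L]] <- list(
          doc = post_doc, tri = c(p$a, rel, p$c), role = "planted_ac")
      }
    }
    for (di in seq_len(spec$n_docs)) {
      doc <- doc_ids[di]
      date <- dates[di]
      novel <- unique(data.frame(
        s = sample(layout$novel_subjects, spec$novel_per_doc, replace = TRUE),
        p = sample(novel_predicates, spec$novel_per_doc, replace = TRUE),
        o = sample(layout$novel_objects, spec$novel_per_doc, replace = TRUE),
        stringsAsFactors = FALSE))
      doc_tris <- lapply(seq_len(nrow(novel)), function(i)
        list(tri = unlist(novel[i, ], use.names = FALSE), role = "novel"))
      for (pl in planted_at)
        if (pl$doc == di) doc_tris <- c(doc_tris, list(pl[c("tri", "role")]))
      # abstract: novel contributions only
      for (i in seq_along(doc_tris))
        add(doc, date, "abstract", i - 1L, doc_tris[[i]]$tri,
            doc_tris[[i]]$role)
      si <- 0L
      for (i in seq_along(doc_tris)) {
        add(doc, date, "body", si, doc_tris[[i]]$tri, doc_tris[[i]]$role)
        si <- si + 1L
      }
      # shared background pool draws, body only
      n_bg <- min(spec$background_per_doc, nrow(layout$pool))
      for (j in sample.int(nrow(layout$pool), n_bg)) {
        add(doc, date, "body", si,
            unlist(layout$pool[j, ], use.names = FALSE), "background")
        si <- si + 1L
      }
      # gap-noise variants of novel triples
      if (spec$noise_rate > 0) {
        for (i in seq_along(doc_tris)) {
          if (doc_tris[[i]]$role != "novel") next
          if (stats::runif(1) < spec$noise_rate) {
            tri <- doc_tris[[i]]$tri
            add(doc, date, "body", si,
                c(noise_variant(tri[1]), tri[2], noise_variant(tri[3])),
                "noise")
            si <- si + 1L
          }
        }
      }
    }
    out <- as_corpus(do.call(rbind, rows))
    role_df <- do.call(rbind, roles)
    role_df <- role_df[!duplicated(triple_key(role_df$subject_cui,
                                              role_df$predicate,
                                              role_df$object_cui)), ,
                       drop = FALSE]
    rownames(role_df) <- NULL
    attr(out, "triple_roles") <- role_df
    out
  })
}

#' Generate the synthetic concept hierarchy
#'
#' A rooted tree over the spec's concepts supporting the depth
#' features: background concepts (generic terms) are direct children
#' of the root (depth 1) and planted/novel concepts hang one level
#' below a background concept (depth 2). Noise-variant concepts are
#' deliberately absent, so predications involving them exercise the
#' missing-feature availability patterns.
#'
#' @param spec a [synthetic_spec()].
#' @return Parent--child data frame with attribute `root`.
#' @export
gen_hierarchy <- function(spec) {
  layout <- synthetic_layout(spec)
  specific <- c(layout$planted$a, layout$planted$b, layout$planted$c,
                layout$novel_subjects, layout$novel_objects)
  df <- rbind(
    data.frame(parent = layout$root, child = layout$background,
               stringsAsFactors = FALSE),
    data.frame(parent = layout$background[
      (seq_along(specific) - 1L) %% length(layout$background) + 1L],
      child = specific, stringsAsFactors = FALSE))
  structure(df, root = layout$root)
}
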