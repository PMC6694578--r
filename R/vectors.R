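#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`, returned as a similarity: higher means more
#' related. Undefined (NA score with a reason) when either vector has zero
#' norm.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single numeric score in `[-1, 1]` (class `lbd_score`).
#' @examples
#' cosine(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
cosine <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) {
    rlang::abort("vectors must have equal dimensionality")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(undefined_score("zero vector"))
  defined_score(sum(u * v) / (nu * nv))
}

# Context vector of `term` over the full vocabulary.
context_vector <- function(matrix, term, directed_rows = FALSE) {
  vocab <- attr(matrix, "vocabulary")
  v <- stats::setNames(numeric(length(vocab)), vocab)
  out_rows <- matrix$term1 == term
  v[matrix$term2[out_rows]] <- v[matrix$term2[out_rows]] + matrix$n[out_rows]
  if (!directed_rows) {
    in_rows <- matrix$term2 == term
    v[matrix$term1[in_rows]] <- v[matrix$term1[in_rows]] + matrix$n[in_rows]
  }
  v
}

#' Direct co-occurrence cosine baseline
#'
#' Represents each term by its co-occurrence context vector — one entry
#' per vocabulary term holding the co-occurrence count with that term —
#' and scores a pair as the cosine of the two vectors. By default the
#' vectors come from the symmetrised matrix (`w_ij + w_ji`), since row
#' direction is an artefact of the counting order; set
#' `directed_rows = TRUE` to use out-rows only.
#'
#' @inheritParams cooc_vocabulary
#' @param a,c Single terms, both in the vocabulary.
#' @param directed_rows Use the directed out-row as the context vector
#'   instead of the symmetrised row? Default `FALSE`.
#' @return A single numeric score (class `lbd_score`); undefined when a
#'   term has an all-zero context.
#' @export
direct_cosine <- function(matrix, a, c, directed_rows = FALSE) {
  check_cooc(matrix)
  a <- as.character(a)
  c <- as.character(c)
  stopifnot(length(a) == 1, length(c) == 1)
  check_terms_known(matrix, c(a, c), "query term")
  if (identical(a, c)) {
    va <- context_vector(matrix, a, directed_rows)
    if (all(va == 0)) return(undefined_score("zero vector"))
    return(defined_score(1))
  }
  cosine(
    context_vector(matrix, a, directed_rows),
    context_vector(matrix, c, directed_rows)
  )
}

#' Embedding tables
#'
#' A dense term-to-vector map, e.g. word2vec-style concept embeddings
#' trained elsewhere and read with [read_embeddings()]. Stored as a
#' numeric matrix with one row per term.
#'
#' @param vectors A numeric matrix with unique rownames (terms), or a
#'   data frame whose first column is the term.
#' @return An `embedding_table`: a numeric matrix with term rownames.
#' @export
embedding_table <- function(vectors) {
  if (is.data.frame(vectors)) {
    terms <- as.character(vectors[[1]])
    vectors <- as.matrix(vectors[-1])
    rownames(vectors) <- terms
  }
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    rlang::abort("embeddings must be a numeric matrix")
  }
  if (is.null(rownames(vectors)) || anyDuplicated(rownames(vectors))) {
    rlang::abort("embeddings must have unique term rownames")
  }
  structure(vectors, class = c("embedding_table", "matrix", "array"))
}

#' Embedding cosine baseline
#'
#' Cosine similarity of two stored embedding vectors. Terms missing from
#' the table give an undefined score with reason `"out of vocabulary"`.
#'
#' @param embeddings An [embedding_table()].
#' @param a,c Single terms.
#' @return A single numeric score (class `lbd_score`).
#' @export
embedding_cosine <- function(embeddings, a, c) {
  if (!inherits(embeddings, "embedding_table")) {
    rlang::abort("expected an `embedding_table`")
  }
  a <- as.character(a)
  c <- as.character(c)
  if (!(a %in% rownames(embeddings)) || !(c %in% rownames(embeddings))) {
    return(undefined_score("out of vocabulary"))
  }
  cosine(embeddings[a, ], embeddings[c, ])
}
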