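#' Directed co-occurrence matrices
#'
#' A co-occurrence matrix records, for an ordered term pair `(i, j)`, the
#' number of times term `i` was followed by term `j` within a counting
#' window. It is the substrate for every association measure in the
#' package. The matrix is stored sparsely as a tibble of positive triplet
#' counts with a vocabulary attribute, so hypothesis-ranking pipelines can
#' pipe it straight into [score_pairs()] or [assoc_table()].
#'
#' @param edges A data frame with columns `term1`, `term2`, `n` giving
#'   directed counts. Counts must be positive; zero cells are simply
#'   absent. Duplicate `(term1, term2)` rows are an error.
#' @param vocabulary Optional character vector of terms. Must contain every
#'   term appearing in `edges`; terms with no edges (isolated vocabulary
#'   members) are allowed and contribute to the vocabulary size used by
#'   linking term association.
#' @return A `cooc_matrix`: a tibble with columns `term1`, `term2`, `n`
#'   (sorted by term pair) carrying a `vocabulary` attribute.
#' @examples
#' m <- cooc_matrix(data.frame(
#'   term1 = c("a", "b"), term2 = c("b", "c"), n = c(2, 1)
#' ))
#' cooc_total(m)
#' @seealso [count_cooccurrences()], [fig2_graph()]
#' @export
cooc_matrix <- function(edges, vocabulary = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("term1", "term2", "n")
  if (!all(required %in% names(edges))) {
    rlang::abort("`edges` must have columns `term1`, `term2`, `n`.")
  }
  edges <- edges[required]
  edges$term1 <- as.character(edges$term1)
  edges$term2 <- as.character(edges$term2)
  edges$n <- as.numeric(edges$n)
  if (any(!is.finite(edges$n)) || any(edges$n < 0)) {
    rlang::abort("co-occurrence counts must be finite and non-negative")
  }
  edges <- edges[edges$n > 0, , drop = FALSE]
  if (anyDuplicated(paste0(edges$term1, "\r", edges$term2))) {
    rlang::abort("duplicate (term1, term2) entries in co-occurrence edges")
  }
  terms_used <- unique(c(edges$term1, edges$term2))
  if (is.null(vocabulary)) {
    vocabulary <- sort(terms_used)
  } else {
    vocabulary <- unique(as.character(vocabulary))
    missing <- setdiff(terms_used, vocabulary)
    if (length(missing) > 0) {
      rlang::abort(paste0(
        "vocabulary is missing terms present in edges: ",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
  }
  edges <- edges[order(edges$term1, edges$term2), , drop = FALSE]
  structure(
    edges,
    vocabulary = vocabulary,
    class = c("cooc_matrix", class(tibble::tibble()))
  )
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf(
    "<cooc_matrix> %d terms, %d directed nonzero cells, total weight %g\n",
    length(attr(x, "vocabulary")), nrow(x), sum(x$n)
  ))
  NextMethod()
}

#' Vocabulary of a co-occurrence matrix
#'
#' @param matrix A [cooc_matrix()].
#' @return Character vector of all vocabulary terms, including any
#'   isolated terms supplied at construction time.
#' @export
cooc_vocabulary <- function(matrix) {
  check_cooc(matrix)
  attr(matrix, "vocabulary")
}

#' Total co-occurrence weight
#'
#' The grand total of all directed counts; the `npp` cell of every
#' weight-based contingency table.
#'
#' @inheritParams cooc_vocabulary
#' @return A single number.
#' @export
cooc_total <- function(matrix) {
  check_cooc(matrix)
  sum(matrix$n)
}

check_cooc <- function(matrix) {
  if (!inherits(matrix, "cooc_matrix")) {
    rlang::abort("expected a `cooc_matrix`; build one with cooc_matrix() or count_cooccurrences()")
  }
  invisible(matrix)
}

check_terms_known <- function(matrix, terms, what = "term") {
  unknown <- setdiff(terms, attr(matrix, "vocabulary"))
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "unknown ", what, "(s) not in vocabulary: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  invisible(terms)
}

#' Count windowed co-occurrences in concept streams
#'
#' Slides a forward-looking window over each document of a tokenised
#' concept stream: for a token at position `p`, every token at positions
#' `p + 1 ... p + window` in the same document increments the directed
#' count (token at `p`, later token) by one. Sentence boundaries are
#' ignored; pairs never cross documents. The default window of 8 follows
#' common practice for concept co-occurrence collection from MEDLINE-style
#' abstracts.
#'
#' A repeated term inside one window produces one count per position pair,
#' so self-pairs `(t, t)` can occur and are stored.
#'
#' @param stream A list of character vectors (one vector of concept
#'   identifiers per document), or a single character vector treated as
#'   one document. Empty documents are allowed and contribute nothing.
#' @param window Positive integer: how many following tokens are paired
#'   with each token. Default 8.
#' @param threshold Non-negative count threshold applied after counting
#'   (see [apply_threshold()]); counts less than or equal to it are
#'   dropped. Default 0 (keep everything).
#' @return A [cooc_matrix()]. With `threshold = 0` its vocabulary is every
#'   token seen in the stream, including tokens that formed no pair.
#' @examples
#' count_cooccurrences(list(c("a", "b", "a", "c")), window = 2)
#' @export
count_cooccurrences <- function(stream, window = 8, threshold = 0) {
  if (is.character(stream)) stream <- list(stream)
  if (!is.list(stream)) rlang::abort("`stream` must be a list of character vectors")
  window <- as.integer(window)
  if (length(window) != 1 || is.na(window) || window < 1) {
    rlang::abort("`window` must be a single integer >= 1")
  }
  pair_list <- lapply(stream, function(doc) {
    doc <- as.character(doc)
    L <- length(doc)
    if (L < 2) return(NULL)
    if (any(!nzchar(doc))) rlang::abort("empty concept identifier in stream")
    # offsets d = 1..window: pair (p, p + d) for p = 1..L-d
    d_max <- min(window, L - 1L)
    first <- unlist(lapply(seq_len(d_max), function(d) doc[seq_len(L - d)]))
    second <- unlist(lapply(seq_len(d_max), function(d) doc[seq.int(d + 1L, L)]))
    list(first = first, second = second)
  })
  pair_list <- pair_list[!vapply(pair_list, is.null, logical(1))]
  vocab <- sort(unique(unlist(lapply(stream, as.character))))
  if (length(pair_list) == 0) {
    m <- cooc_matrix(
      tibble::tibble(term1 = character(), term2 = character(), n = numeric()),
      vocabulary = vocab
    )
    return(if (threshold > 0) apply_threshold(m, threshold) else m)
  }
  first <- unlist(lapply(pair_list, `[[`, "first"))
  second <- unlist(lapply(pair_list, `[[`, "second"))
  counts <- table(paste0(first, "\r", second))
  key <- strsplit(names(counts), "\r", fixed = TRUE)
  m <- cooc_matrix(
    tibble::tibble(
      term1 = vapply(key, `[[`, character(1), 1),
      term2 = vapply(key, `[[`, character(1), 2),
      n = as.numeric(counts)
    ),
    vocabulary = vocab
  )
  if (threshold > 0) apply_threshold(m, threshold) else m
}

#' Remove low-frequency co-occurrence cells
#'
#' Every count less than or equal to `threshold` is set to zero (removed
#' from the sparse representation); larger counts are untouched. The usual
#' noise filter before computing association measures uses `threshold = 1`.
#'
#' By default the vocabulary is recomputed from the surviving cells, so a
#' term whose every co-occurrence falls at or below the threshold leaves
#' the vocabulary (and therefore shrinks the `|V|` total used by linking
#' term association). Set `keep_vocabulary = TRUE` to retain the original
#' vocabulary instead.
#'
#' @inheritParams cooc_vocabulary
#' @param threshold Non-negative number.
#' @param keep_vocabulary Keep the pre-thresholding vocabulary? Default
#'   `FALSE`.
#' @return A [cooc_matrix()].
#' @export
apply_threshold <- function(matrix, threshold = 1, keep_vocabulary = FALSE) {
  check_cooc(matrix)
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0) {
    rlang::abort("`threshold` must be a single non-negative number")
  }
  kept <- matrix[matrix$n > threshold, , drop = FALSE]
  vocab <- if (keep_vocabulary) attr(matrix, "vocabulary") else NULL
  cooc_matrix(tibble::as_tibble(kept), vocabulary = vocab)
}

#' Symmetrise a directed co-occurrence matrix
#'
#' Adds the transpose: the returned matrix has `w_ij + w_ji` in cell
#' `(i, j)`. Useful when token order in the source corpus carries no
#' meaning, and used by default for direct-cosine context vectors.
#'
#' @inheritParams cooc_vocabulary
#' @return A symmetric [cooc_matrix()] over the same vocabulary.
#' @export
cooc_symmetrize <- function(matrix) {
  check_cooc(matrix)
  both <- dplyr::bind_rows(
    tibble::as_tibble(matrix),
    tibble::tibble(term1 = matrix$term2, term2 = matrix$term1, n = matrix$n)
  )
  agg <- dplyr::summarise(
    dplyr::group_by(both, .data$term1, .data$term2),
    n = sum(.data$n), .groups = "drop"
  )
  cooc_matrix(agg, vocabulary = attr(matrix, "vocabulary"))
}

#' Marginal weights for a set of terms
#'
#' Computes the three marginal totals that feed weight-based contingency
#' tables: the summed weight of all edges leaving the term set
#' (`out_weight`, the first-position marginal), the summed weight of all
#' edges entering it (`in_weight`, the second-position marginal), and the
#' grand total over the whole matrix (`total`, independent of `terms`).
#'
#' @inheritParams cooc_vocabulary
#' @param terms Character vector of terms; all must be in the vocabulary.
#' @return A one-row tibble with columns `out_weight`, `in_weight`,
#'   `total`.
#' @examples
#' g <- fig2_graph()
#' cooc_marginals(g, "A")  # out_weight 14, total 30
#' @export
cooc_marginals <- function(matrix, terms) {
  check_cooc(matrix)
  terms <- unique(as.character(terms))
  check_terms_known(matrix, terms)
  tibble::tibble(
    out_weight = sum(matrix$n[matrix$term1 %in% terms]),
    in_weight = sum(matrix$n[matrix$term2 %in% terms]),
    total = sum(matrix$n)
  )
}

#' Linking sets for a start/target query
#'
#' In the ABC discovery model, a linking term connects a start term set
#' `A` to a target set `C` through direct co-occurrence with both.
#' `b_a` is the set of terms preceded by any member of `A` (out-neighbours
#' of `A`); `b_c` the set of terms preceding any member of `C`
#' (in-neighbours of `C`); `shared` their intersection — the linking
#' terms. Query terms themselves (`A` and `C`) are excluded from all three
#' sets: a linking term connects two *other* terms.
#'
#' @inheritParams cooc_vocabulary
#' @param a,c Character vectors of start and target terms. Must be
#'   non-empty, disjoint, and in the vocabulary.
#' @return A list of class `linking_sets` with character-vector fields
#'   `b_a`, `b_c`, `shared`.
#' @examples
#' ls <- linking_sets(fig2_graph(), "A", "C")
#' length(ls$shared)  # 2
#' @export
linking_sets <- function(matrix, a, c) {
  check_cooc(matrix)
  a <- unique(as.character(a))
  c <- unique(as.character(c))
  if (length(a) == 0 || length(c) == 0) {
    rlang::abort("start and target sets must be non-empty")
  }
  if (length(intersect(a, c)) > 0) {
    rlang::abort("start and target sets must be disjoint")
  }
  check_terms_known(matrix, c(a, c), "query term")
  query <- c(a, c)
  b_a <- setdiff(unique(matrix$term2[matrix$term1 %in% a]), query)
  b_c <- setdiff(unique(matrix$term1[matrix$term2 %in% c]), query)
  structure(
    list(b_a = sort(b_a), b_c = sort(b_c), shared = sort(intersect(b_a, b_c))),
    class = "linking_sets"
  )
}

#' @export
print.linking_sets <- function(x, ...) {
  cat(sprintf(
    "<linking_sets> |B_A| = %d, |B_C| = %d, shared = %d\n",
    length(x$b_a), length(x$b_c), length(x$shared)
  ))
  invisible(x)
}
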