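#' The worked-example co-occurrence graph
#'
#' A nine-term directed graph used throughout the documentation and tests:
#' start term `A` co-occurs with four linking candidates (`b1`-`b4`, with
#' weights 1, 2, 8, 3), target term `C` is preceded by three (`b3`, `b4`,
#' `b5`, with weights 4, 5, 7), so `b3` and `b4` are the shared linking
#' terms, and one isolated `gray` term sits in the vocabulary without
#' co-occurring with anything. `A` and `C` never directly co-occur, which
#' is exactly the ABC discovery setting.
#'
#' Reference quantities: total weight 30; out-weight of `A` 14; in-weight
#' of `C` 16; linking term count 2; MWA joint cell `min(8,4) + min(3,5)
#' = 7`.
#'
#' @return A [cooc_matrix()] with vocabulary
#'   `A, b1, b2, b3, b4, b5, gray, C` (9 terms including the isolated
#'   one).
#' @examples
#' g <- fig2_graph()
#' ltc(g, "A", "C")
#' @export
fig2_graph <- function() {
  cooc_matrix(
    tibble::tibble(
      term1 = c("A", "A", "A", "A", "b3", "b4", "b5"),
      term2 = c("b1", "b2", "b3", "b4", "C", "C", "C"),
      n = c(1, 2, 8, 3, 4, 5, 7)
    ),
    vocabulary = c("A", "b1", "b2", "b3", "b4", "b5", "gray", "C")
  )
}

#' Random ABC-topology graphs for property testing
#'
#' Generates a co-occurrence graph with the same role structure as the
#' worked example: `n_white` terms co-occur with `A` only, `n_shared`
#' terms with both `A` and `C` (the linking terms), `n_black` terms with
#' `C` only, and `n_gray` terms are isolated vocabulary members. Edge
#' weights are drawn uniformly from `weight_range`. Identical arguments
#' and seed give an identical matrix.
#'
#' @param n_white,n_shared,n_black,n_gray Non-negative role counts.
#' @param weight_range Integer range `c(lo, hi)` with `lo >= 1`.
#' @param seed Integer seed.
#' @return A [cooc_matrix()] with terms `A`, `C`, `w1..`, `s1..`, `k1..`,
#'   `g1..`.
#' @export
random_lbd_graph <- function(n_white = 2, n_shared = 2, n_black = 1,
                             n_gray = 1, weight_range = c(1, 9), seed = 1) {
  counts <- c(n_white, n_shared, n_black, n_gray)
  if (any(counts < 0)) rlang::abort("role counts must be non-negative")
  if (weight_range[1] < 1) rlang::abort("weights must be >= 1")
  white <- if (n_white > 0) paste0("w", seq_len(n_white)) else character()
  shared <- if (n_shared > 0) paste0("s", seq_len(n_shared)) else character()
  black <- if (n_black > 0) paste0("k", seq_len(n_black)) else character()
  gray <- if (n_gray > 0) paste0("g", seq_len(n_gray)) else character()
  a_targets <- c(white, shared)
  c_sources <- c(shared, black)
  with_seed(seed, {
    weights <- seq.int(weight_range[1], weight_range[2])
    draw <- function(k) {
      if (k == 0) return(numeric())
      # sample() would treat a single-value pool as 1:n
      if (length(weights) == 1) rep(weights, k) else sample(weights, k, replace = TRUE)
    }
    edges <- tibble::tibble(
      term1 = c(rep("A", length(a_targets)), c_sources),
      term2 = c(a_targets, rep("C", length(c_sources))),
      n = c(draw(length(a_targets)), draw(length(c_sources)))
    )
    cooc_matrix(edges, vocabulary = c("A", white, shared, black, gray, "C"))
  })
}

#' Random concept streams for property testing
#'
#' Reproducible uniform token streams: `n_docs` documents of `doc_len`
#' tokens each, drawn from a vocabulary `t1..t<vocab_size>`. Used to
#' exercise windowed counting against a brute-force position-pair oracle.
#'
#' @param n_docs Non-negative number of documents.
#' @param doc_len Positive document length (tokens).
#' @param vocab_size Positive vocabulary size.
#' @param seed Integer seed.
#' @return A list of character vectors, one per document.
#' @export
random_streams <- function(n_docs, doc_len, vocab_size, seed = 1) {
  if (doc_len < 1 || vocab_size < 1 || n_docs < 0) {
    rlang::abort("n_docs must be >= 0; doc_len and vocab_size must be >= 1")
  }
  vocab <- paste0("t", seq_len(vocab_size))
  with_seed(seed, {
    lapply(seq_len(n_docs), function(i) sample(vocab, doc_len, replace = TRUE))
  })
}
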